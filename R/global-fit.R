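# Global (joint) fitting: one shared |J| per coupling group, one shared R
# per decay group, one free amplitude per dataset.  The default grouping
# mirrors how the measured parameters are reported: J is a property of a
# (complex, proton->carbon channel) shared over temperatures and detection
# modes; R is a property of (complex, temperature, detection mode) shared
# over channels.

default_j_group <- function(d)
  paste(d$complex_id, d$proton, d$carbon, sep = ":")

default_r_group <- function(d)
  paste(d$complex_id, d$temperature_K,
        if (isTRUE(d$decoupled)) "dec" else "coup", sep = ":")

#' Global fit of several kinetics datasets with shared parameters
#'
#' Joint least squares of the damped-sinusoid model over all datasets,
#' with J tied within `j_group`, R tied within `r_group` and a free
#' amplitude per dataset.  Starting values come from per-dataset single
#' fits (group medians); standard errors from the joint Jacobian at the
#' optimum.  A J group none of whose datasets carries a significant
#' oscillation is flagged unidentifiable.
#'
#' @param datasets list of `kinetics_dataset` objects.
#' @param j_group,r_group character vectors (one entry per dataset)
#'   naming the sharing group of each dataset, or functions
#'   `dataset -> name`.  Defaults: J by (complex, channel); R by
#'   (complex, temperature, detection mode).
#' @return An object of class `global_fit_result`: `j_report` /
#'   `r_report` data frames (group, estimate, se, identifiable),
#'   `amplitudes` per dataset, `coefficients`, `cov`, `sse`,
#'   `residual_rms`, `converged`, and `single_fits` (the per-dataset fits
#'   used for initialization).
#' @export
fit_global <- function(datasets, j_group = default_j_group,
                       r_group = default_r_group) {
  stopifnot(length(datasets) >= 1)
  jg <- if (is.function(j_group)) vapply(datasets, j_group, character(1))
        else as.character(j_group)
  rg <- if (is.function(r_group)) vapply(datasets, r_group, character(1))
        else as.character(r_group)
  if (length(jg) != length(datasets) || length(rg) != length(datasets))
    stop("group vectors must have one entry per dataset")
  j_levels <- unique(jg)
  r_levels <- unique(rg)
  singles <- lapply(datasets, fit_single)
  j_ident <- vapply(j_levels, function(g)
    any(vapply(singles[jg == g], function(f) isTRUE(f$identifiable),
               logical(1))), logical(1))
  start_j <- vapply(j_levels, function(g) {
    v <- vapply(singles[jg == g], function(f)
      if (isTRUE(f$converged)) f$coefficients[["J"]] else NA_real_,
      numeric(1))
    v <- v[is.finite(v)]
    if (length(v) == 0) 1 else stats::median(v)
  }, numeric(1))
  start_r <- vapply(r_levels, function(g) {
    v <- vapply(singles[rg == g], function(f)
      if (isTRUE(f$converged)) f$coefficients[["R"]] else NA_real_,
      numeric(1))
    v <- v[is.finite(v)]
    if (length(v) == 0) 1 else stats::median(v)
  }, numeric(1))
  start_a <- vapply(singles, function(f)
    if (isTRUE(f$converged)) f$coefficients[["A"]] else 1, numeric(1))

  nj <- length(j_levels); nr <- length(r_levels); nd <- length(datasets)
  ji <- match(jg, j_levels); ri <- match(rg, r_levels)
  pack <- function(j, r, a) c(j, r, a)
  unpack <- function(p) list(j = p[seq_len(nj)],
                             r = p[nj + seq_len(nr)],
                             a = p[nj + nr + seq_len(nd)])
  resid_fn <- function(p) {
    q <- unpack(p)
    unlist(lapply(seq_len(nd), function(d) {
      tau <- datasets[[d]]$tau2_s
      datasets[[d]]$signal -
        q$a[d] * sin(2 * pi * q$j[ji[d]] * tau) *
          exp(-2 * tau * q$r[ri[d]])
    }))
  }
  jac_fn <- function(p) {
    q <- unpack(p)
    blocks <- lapply(seq_len(nd), function(d) {
      tau <- datasets[[d]]$tau2_s
      m <- matrix(0, length(tau), nj + nr + nd)
      s <- sin(2 * pi * q$j[ji[d]] * tau)
      cc <- cos(2 * pi * q$j[ji[d]] * tau)
      e <- exp(-2 * tau * q$r[ri[d]])
      m[, ji[d]] <- -q$a[d] * 2 * pi * tau * cc * e
      m[, nj + ri[d]] <- 2 * tau * q$a[d] * s * e
      m[, nj + nr + d] <- -s * e
      m
    })
    do.call(rbind, blocks)
  }
  lower <- c(rep(.j_bounds[1], nj), rep(.r_bounds[1], nr), rep(-Inf, nd))
  upper <- c(rep(.j_bounds[2], nj), rep(.r_bounds[2], nr), rep(Inf, nd))
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = pack(start_j, start_r, start_a),
    lower = lower, upper = upper,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                         ptol = 1e-14)))
  p <- res$par
  q <- unpack(p)
  n_total <- sum(vapply(datasets, function(d) length(d$signal), integer(1)))
  npar <- nj + nr + nd
  s2 <- res$deviance / max(n_total - npar, 1)
  jac <- jac_fn(p)
  covm <- try(solve(crossprod(jac)) * s2, silent = TRUE)
  if (inherits(covm, "try-error")) covm <- matrix(NA, npar, npar)
  se <- sqrt(pmax(diag(covm), 0))
  qs <- unpack(se)
  # group-level ridge screen: J group degenerate with every amplitude it
  # is tied to (see fit_single for the single-dataset analogue).  When the
  # joint covariance is unavailable (e.g. an all-zero group makes it
  # singular) the per-dataset screens in `singles` already decide.
  ridge_g <- vapply(seq_len(nj), function(g) {
    if (anyNA(covm)) return(FALSE)
    ds <- which(ji == g)
    corr <- vapply(ds, function(d) {
      den <- sqrt(covm[g, g] * covm[nj + nr + d, nj + nr + d])
      if (!is.finite(den) || den <= 0) return(1)
      abs(covm[g, nj + nr + d] / den)
    }, numeric(1))
    all(!is.finite(corr) | corr > .ridge_corr_threshold)
  }, logical(1))
  j_report <- data.frame(group = j_levels, J_hz = abs(q$j), se = qs$j,
                         identifiable = j_ident & !ridge_g,
                         row.names = NULL)
  r_report <- data.frame(group = r_levels, R_per_s = q$r, se = qs$r,
                         row.names = NULL)
  amplitudes <- data.frame(dataset = seq_len(nd), j_group = jg,
                           r_group = rg, A = q$a, se = qs$a)
  structure(list(j_report = j_report, r_report = r_report,
                 amplitudes = amplitudes,
                 coefficients = p, cov = covm, sse = res$deviance,
                 residual_rms = sqrt(res$deviance / n_total),
                 converged = res$info %in% 1:4,
                 single_fits = singles),
            class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result>\n  shared couplings:\n")
  print(transform(x$j_report, J_hz = round(J_hz, 4), se = signif(se, 3)),
        row.names = FALSE)
  cat("  shared decay rates:\n")
  print(transform(x$r_report, R_per_s = round(R_per_s, 4),
                  se = signif(se, 3)), row.names = FALSE)
  invisible(x)
}
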