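# Physical constants used across the package (CODATA 2018 where applicable).
.kB <- 1.380649e-23      # J/K
.h_planck <- 6.62607015e-34  # J s
.R_gas <- 8.314462618    # J/(mol K)

# gamma(13C)/gamma(1H); fixed so the 13C Larmor frequency derives from the
# proton frequency without a second field parameter.
.gamma_ratio <- c(H1 = 1.0, C13 = 0.2514)

#' Define a small spin-1/2 system
#'
#' A spin system is the static description from which every Hamiltonian,
#' pulse and acquisition in the simulator is built: an ordered set of
#' spin-1/2 nuclei (1H or 13C) with chemical shifts, a symmetric scalar
#' coupling (J) matrix in Hz, and the spectrometer field expressed as the
#' proton Larmor frequency.
#'
#' @param spins data frame with columns `label` (unique character),
#'   `isotope` (`"H1"` or `"C13"`) and `shift_ppm` (numeric).
#' @param j_matrix symmetric numeric matrix of scalar couplings in Hz with
#'   zero diagonal, one row/column per spin in the order of `spins`.
#'   Dimnames, if present, must match the labels.
#' @param field_proton_mhz proton Larmor frequency in MHz; 400 corresponds
#'   to the 9.4 T field used for the Ir-pyruvate measurements.
#' @param carrier_ppm optional named numeric vector of per-isotope carrier
#'   (reference) offsets in ppm, e.g. `c(H1 = -28.15)`.  Isotopes without an
#'   entry default, at detection time, to the mean shift of the spins of
#'   that isotope.
#'
#' @return An object of class `spin_system`.
#' @export
#' @examples
#' sys <- spin_system(
#'   spins = data.frame(label = c("Ha", "Hb"), isotope = "H1",
#'                      shift_ppm = c(-29.10, -27.20)),
#'   j_matrix = matrix(c(0, -10.48, -10.48, 0), 2, 2)
#' )
#' offsets_hz(sys)
spin_system <- function(spins, j_matrix, field_proton_mhz = 400.0,
                        carrier_ppm = NULL) {
  spins <- as.data.frame(spins, stringsAsFactors = FALSE)
  required <- c("label", "isotope", "shift_ppm")
  if (!all(required %in% names(spins)))
    stop("`spins` needs columns: ", paste(required, collapse = ", "))
  spins$label <- as.character(spins$label)
  spins$isotope <- as.character(spins$isotope)
  if (anyDuplicated(spins$label))
    stop("spin labels must be unique")
  if (!all(spins$isotope %in% c("H1", "C13")))
    stop("isotopes must be 'H1' or 'C13'")
  n <- nrow(spins)
  j_matrix <- as.matrix(j_matrix)
  if (!is.numeric(j_matrix) || any(!is.finite(j_matrix)))
    stop("j_matrix must be finite numeric")
  if (nrow(j_matrix) != n || ncol(j_matrix) != n)
    stop("j_matrix must be ", n, "x", n)
  if (max(abs(j_matrix - t(j_matrix))) > 1e-9)
    stop("j_matrix must be symmetric")
  if (any(abs(diag(j_matrix)) > 0))
    stop("j_matrix must have zero diagonal")
  if (!is.null(dimnames(j_matrix)) &&
      !identical(rownames(j_matrix), spins$label))
    stop("j_matrix dimnames must match spin labels")
  dimnames(j_matrix) <- list(spins$label, spins$label)
  stopifnot(is.numeric(field_proton_mhz), field_proton_mhz > 0)
  if (!is.null(carrier_ppm)) {
    if (is.null(names(carrier_ppm)) ||
        !all(names(carrier_ppm) %in% c("H1", "C13")))
      stop("carrier_ppm must be named by isotope ('H1', 'C13')")
  }
  structure(
    list(spins = spins, j_matrix = j_matrix,
         field_proton_mhz = as.numeric(field_proton_mhz),
         carrier_ppm = carrier_ppm),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d spins at %.1f MHz (1H)\n",
              nrow(x$spins), x$field_proton_mhz))
  print(x$spins, row.names = FALSE)
  cat("J matrix (Hz):\n")
  print(round(x$j_matrix, 4))
  invisible(x)
}

n_spins <- function(system) nrow(system$spins)

spin_index <- function(system, label) {
  idx <- match(label, system$spins$label)
  if (anyNA(idx))
    stop("unknown spin label(s): ",
         paste(label[is.na(idx)], collapse = ", "))
  idx
}

#' Larmor frequency of an isotope in this system
#'
#' @param system a [spin_system()].
#' @param isotope `"H1"` or `"C13"`.
#' @return Larmor frequency in MHz.
#' @export
larmor_mhz <- function(system, isotope) {
  ratio <- .gamma_ratio[[isotope]]
  if (is.null(ratio)) stop("unknown isotope: ", isotope)
  system$field_proton_mhz * ratio
}

carrier_for <- function(system, isotope) {
  if (!is.null(system$carrier_ppm) && isotope %in% names(system$carrier_ppm))
    return(system$carrier_ppm[[isotope]])
  sel <- system$spins$isotope == isotope
  if (!any(sel)) return(0)
  mean(system$spins$shift_ppm[sel])
}

#' Rotating-frame offsets of all spins in Hz
#'
#' Offsets are `(shift_ppm - carrier_ppm) * larmor(isotope)`, computed per
#' isotope against the system carrier (default: the mean shift of the spins
#' of that isotope).
#'
#' @param system a [spin_system()].
#' @return Named numeric vector of offsets in Hz, one per spin.
#' @export
offsets_hz <- function(system) {
  off <- vapply(seq_len(n_spins(system)), function(i) {
    iso <- system$spins$isotope[i]
    (system$spins$shift_ppm[i] - carrier_for(system, iso)) *
      larmor_mhz(system, iso)
  }, numeric(1))
  names(off) <- system$spins$label
  off
}

#' Read a spin system from a YAML or JSON config file
#'
#' The config carries `spins` (list of `label`/`isotope`/`shift_ppm`),
#' `j_couplings` (list of `a`/`b`/`j_hz` upper-triangle entries),
#' `field_proton_mhz` and optionally `carrier_ppm`.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml`/`.json`).
#' @return A [spin_system()].
#' @export
read_spin_system <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported config extension: ", ext)
  )
  if (is.null(cfg$spins)) stop("config lacks 'spins'")
  spins <- do.call(rbind, lapply(cfg$spins, function(s)
    data.frame(label = s$label, isotope = s$isotope,
               shift_ppm = as.numeric(s$shift_ppm))))
  n <- nrow(spins)
  jm <- matrix(0, n, n, dimnames = list(spins$label, spins$label))
  for (e in cfg$j_couplings %||% list()) {
    jm[e$a, e$b] <- jm[e$b, e$a] <- as.numeric(e$j_hz)
  }
  carrier <- cfg$carrier_ppm
  if (!is.null(carrier)) carrier <- unlist(carrier)
  spin_system(spins, jm,
              field_proton_mhz = cfg$field_proton_mhz %||% 400.0,
              carrier_ppm = carrier)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
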