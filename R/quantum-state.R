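# Single-spin Cartesian operators in the convention Iz = diag(1/2, -1/2),
# [Ix, Iy] = i Iz.  All multi-spin operators are Kronecker products in the
# spin order of the system.
.sigma <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = diag(c(0.5, -0.5)),
  e = diag(2)
)

# Product operator: for each spin, one of "x","y","z","e" (identity).
# axes is a named-by-index character vector/list, e.g. c(`1`="z", `3`="y").
prod_op <- function(n, axes) {
  ops <- rep(list(.sigma$e), n)
  for (nm in names(axes)) ops[[as.integer(nm)]] <- .sigma[[axes[[nm]]]]
  Reduce(`%x%`, ops)
}

# Single-spin operator embedded in the n-spin space.
spin_op <- function(n, i, axis) {
  prod_op(n, stats::setNames(list(axis), as.character(i)))
}

#' Wrap a density matrix as a quantum state
#'
#' States use the traceless deviation-density convention: the identity
#' component carries no signal and is dropped, so valid states are Hermitian
#' with zero trace.  Amplitudes are therefore relative, never absolute.
#'
#' @param matrix complex square matrix of dimension `2^N`.
#' @param system the [spin_system()] fixing the basis ordering.
#' @return An object of class `quantum_state`.
#' @export
quantum_state <- function(matrix, system) {
  n <- n_spins(system)
  dim_expect <- 2^n
  if (nrow(matrix) != dim_expect || ncol(matrix) != dim_expect)
    stop("state dimension must be 2^", n, " = ", dim_expect)
  if (max(Mod(matrix - Conj(t(matrix)))) > 1e-12)
    stop("state must be Hermitian (within 1e-12)")
  if (Mod(sum(diag(matrix))) > 1e-10)
    stop("state must be traceless (deviation-density convention)")
  structure(list(matrix = matrix, labels = system$spins$label),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat(sprintf("<quantum_state> %d spins (%s), purity tr(rho^2) = %.6g\n",
              length(x$labels), paste(x$labels, collapse = ","),
              purity(x)))
  invisible(x)
}

#' Purity tr(rho^2) of a state
#'
#' Conserved by pulses and undamped evolution; a convenient unitarity check.
#'
#' @param state a [quantum_state()].
#' @return Real scalar.
#' @export
purity <- function(state) {
  Re(sum(diag(state$matrix %*% state$matrix)))
}

#' Parahydrogen-derived longitudinal two-spin order
#'
#' High-field addition of parahydrogen to the Ir complex leaves the two
#' hydride protons in longitudinal two-spin order Iz(a)Iz(b): unobservable
#' until pulses and J evolution convert it.  For a two-spin system this is
#' the diagonal matrix `diag(1, -1, -1, 1)/4`.
#'
#' @param system a [spin_system()].
#' @param spin_a,spin_b labels of the two (distinct) 1H spins.
#' @return A [quantum_state()] equal to the product operator `Iz^a Iz^b`.
#' @export
initial_ph2_order <- function(system, spin_a, spin_b) {
  ia <- spin_index(system, spin_a)
  ib <- spin_index(system, spin_b)
  if (ia == ib) stop("spin_a and spin_b must be distinct")
  iso <- system$spins$isotope[c(ia, ib)]
  if (!all(iso == "H1"))
    stop("parahydrogen order lives on 1H spins; got: ",
         paste(iso, collapse = ", "))
  n <- n_spins(system)
  m <- prod_op(n, stats::setNames(list("z", "z"), c(ia, ib)))
  quantum_state(m, system)
}

#' Coefficient of a product operator in a state
#'
#' Projects the state onto a Cartesian product operator given as per-spin
#' axes, using the Frobenius inner product: `Re tr(rho B) / tr(B B)` where
#' `B` is the product of the named single-spin operators times
#' `2^(k-1)` for `k` non-identity factors (the conventional normalized
#' product-operator basis, e.g. `2 Iz Sy`).
#'
#' @param state a [quantum_state()].
#' @param system the matching [spin_system()].
#' @param ... named axes, e.g. `Ha = "z", C2 = "y"` for `2 Iz(Ha) Iy(C2)`.
#' @return Real coefficient.
#' @export
op_coefficient <- function(state, system, ...) {
  axes <- list(...)
  idx <- spin_index(system, names(axes))
  n <- n_spins(system)
  b <- prod_op(n, stats::setNames(axes, idx)) * 2^(length(axes) - 1)
  Re(sum(diag(state$matrix %*% b))) / Re(sum(diag(b %*% b)))
}
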