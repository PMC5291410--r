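# Core gene-circuit model: parameters, regulation-expression kinetics, and the
# right-hand side of the hybrid ODE system.

GAP_GENES <- c("hb", "Kr", "gt", "kni")
EXTERNAL_REGULATORS <- c("Bcd", "Cad", "Tll", "Hkb")

#' Circuit parameters
#'
#' Container for all constants of the gene-circuit ODE: per-gene production
#' rates `R`, diffusion coefficients at the final cleavage cycle `D_base`,
#' decay rates `lambda`, the gene-gene interconnectivity matrix `W` (rows are
#' target genes, columns regulators), the external-input matrix `E` (columns
#' follow `external_names`), and the per-gene threshold `h`. An optional
#' `sign_mask` (list with entries `W` and `E`, values in -1/0/+1, where 0
#' leaves the entry unconstrained) records sign constraints on regulatory
#' weights.
#'
#' @param R numeric vector, per-gene maximum production rate (au/min, >= 0).
#' @param lambda numeric vector, per-gene decay rate (1/min, > 0).
#' @param W numeric matrix of gene-gene regulatory weights, entry `[a, b]` is
#'   the effect of regulator `b` on target `a`.
#' @param E numeric matrix of external-input weights, entry `[a, m]` is the
#'   effect of external regulator `m` on target `a`.
#' @param h numeric vector, per-gene threshold/bias.
#' @param D_base numeric vector, per-gene diffusion coefficient during the
#'   final cleavage cycle (1/min, >= 0); zero for diffusion-less circuits.
#' @param gene_names character vector of gene identifiers.
#' @param external_names character vector naming the columns of `E`.
#' @param sign_mask optional list with matrices `W` and `E` of -1/0/+1 sign
#'   constraints.
#' @return an object of class `circuit_parameters`.
#' @export
circuit_parameters <- function(R, lambda, W, E, h,
                               D_base = rep(0, length(R)),
                               gene_names = NULL,
                               external_names = NULL,
                               sign_mask = NULL) {
  G <- length(R)
  if (is.null(gene_names)) {
    gene_names <- if (G == 4L) GAP_GENES else paste0("g", seq_len(G))
  }
  W <- as.matrix(W)
  E <- as.matrix(E)
  if (ncol(E) == 0L) E <- matrix(0, G, 0)
  if (is.null(external_names)) {
    external_names <- if (ncol(E) == 4L) EXTERNAL_REGULATORS else
      as.character(sprintf("m%d", seq_len(ncol(E))))
  }
  p <- structure(
    list(gene_names = gene_names, external_names = external_names,
         R = as.numeric(R), D_base = as.numeric(D_base),
         lambda = as.numeric(lambda), W = unname(W), E = unname(E),
         h = as.numeric(h), sign_mask = sign_mask),
    class = "circuit_parameters")
  validate_parameters(p)
  p
}

#' Validate circuit parameters
#'
#' Checks the structural invariants: `R >= 0`, `lambda > 0`, `D_base >= 0`,
#' conforming matrix dimensions, and (if a sign mask is present) agreement of
#' `sign(W)` and `sign(E)` with the mask wherever the mask is non-zero.
#'
#' @param p a `circuit_parameters` object.
#' @return `p`, invisibly; stops with a validation error otherwise.
#' @export
validate_parameters <- function(p) {
  G <- length(p$R)
  M <- ncol(p$E)
  stopifnot(length(p$lambda) == G, length(p$h) == G, length(p$D_base) == G,
            length(p$gene_names) == G, length(p$external_names) == M)
  if (any(!is.finite(p$R)) || any(p$R < 0))
    stop("production rates R must be finite and >= 0")
  if (any(!is.finite(p$lambda)) || any(p$lambda <= 0))
    stop("decay rates lambda must be finite and > 0")
  if (any(!is.finite(p$D_base)) || any(p$D_base < 0))
    stop("diffusion coefficients D must be finite and >= 0")
  if (!all(dim(p$W) == c(G, G))) stop("W must be ", G, "x", G)
  if (nrow(p$E) != G) stop("E must have one row per gene")
  if (!is.null(p$sign_mask)) {
    for (nm in c("W", "E")) {
      mask <- p$sign_mask[[nm]]
      if (is.null(mask)) next
      val <- p[[nm]]
      if (!all(dim(mask) == dim(val)))
        stop("sign_mask$", nm, " dimensions do not match ", nm)
      bad <- mask != 0 & sign(val) != 0 & sign(val) != mask
      if (any(bad))
        stop("sign constraint violated in ", nm, " at ",
             paste(which(bad), collapse = ", "))
    }
  }
  invisible(p)
}

#' Sigmoid regulation-expression function
#'
#' The coarse-grained transcription kinetics \eqn{\phi(u) =
#' \frac{1}{2}\left(\frac{u}{\sqrt{u^2+1}} + 1\right)}, strictly increasing
#' and bounded in (0, 1), with \eqn{\phi(0) = 1/2} and
#' \eqn{\phi(u) + \phi(-u) = 1}.
#'
#' @param u numeric vector of total regulatory inputs.
#' @return values of the same shape as `u`, in (0, 1).
#' @export
regulation_expression <- function(u) {
  if (any(!is.finite(u))) stop("non-finite regulatory input u")
  0.5 * (u / sqrt(u * u + 1) + 1)
}

#' Derivative of the regulation-expression function
#'
#' \eqn{\phi'(u) = \frac{1}{2}(u^2+1)^{-3/2}}, always positive, with its
#' maximum 1/2 at u = 0. Used for the analytic Jacobians of the phase
#' portrait analysis.
#'
#' @inheritParams regulation_expression
#' @return positive values of the same shape as `u`.
#' @export
regulation_expression_derivative <- function(u) {
  if (any(!is.finite(u))) stop("non-finite regulatory input u")
  0.5 * (u * u + 1)^(-1.5)
}

#' Total regulatory input for target genes
#'
#' Computes \eqn{u^a = \sum_b W_{ab} g^b + \sum_m E_{am} g^m + h^a} for one or
#' all target genes.
#'
#' @param gap_state numeric vector of gap-protein concentrations (length G).
#' @param external_state numeric vector of external-regulator concentrations
#'   (length M).
#' @param params a `circuit_parameters` object.
#' @param target gene index or name; `NULL` returns all targets.
#' @return numeric scalar (single target) or length-G vector.
#' @export
total_input <- function(gap_state, external_state, params, target = NULL) {
  G <- length(params$R)
  if (length(gap_state) != G) stop("gap_state must have length ", G)
  if (length(external_state) != ncol(params$E))
    stop("external_state must have length ", ncol(params$E))
  u <- drop(params$W %*% gap_state) + params$h
  if (ncol(params$E) > 0) u <- u + drop(params$E %*% external_state)
  if (is.null(target)) return(u)
  if (is.character(target)) target <- match(target, params$gene_names)
  u[target]
}

#' Diffusion coefficient at a given cleavage cycle
#'
#' Diffusion enters the equations through a discrete Laplacian over
#' neighbouring nuclei. Because the inter-nucleus distance halves at each
#' division, the Laplacian coefficient scales as \eqn{1/\Delta x^2}: one fewer
#' division means a 4-fold smaller coefficient. `D_base` refers to the final
#' cycle (`n_final`).
#'
#' @param params a `circuit_parameters` object.
#' @param cycle_index number of preceding divisions n.
#' @param n_final the cycle index at which `D_base` applies (default 14).
#' @return per-gene diffusion rates.
#' @export
diffusion_coefficient <- function(params, cycle_index, n_final = 14L) {
  params$D_base * 4^(cycle_index - n_final)
}

#' Right-hand side of the circuit ODE
#'
#' Reference (pure R) evaluation of the interphase/mitosis dynamics
#' \eqn{dg^a_i/dt = R^a \phi(u^a_i) + D^a(n)(g^a_{i-1} + g^a_{i+1} - 2 g^a_i)
#' - \lambda^a g^a_i}, with production switched off during mitosis and
#' zero-flux boundaries (the absent neighbour is mirrored). The compiled
#' integrator re-implements the same expression; this function is the
#' readable reference used in tests and for small systems.
#'
#' @param state numeric matrix, nuclei x genes, non-negative.
#' @param external_at_t numeric matrix, nuclei x external regulators.
#' @param params a `circuit_parameters` object.
#' @param row a `nucleus_row` (used for the cycle-dependent diffusion rate).
#' @param phase `"interphase"` or `"mitosis"`.
#' @return matrix of time derivatives, same shape as `state`.
#' @export
circuit_rhs <- function(state, external_at_t, params, row,
                        phase = c("interphase", "mitosis")) {
  phase <- match.arg(phase)
  state <- as.matrix(state)
  if (any(state < 0)) stop("negative concentrations in state")
  n <- nrow(state)
  u <- state %*% t(params$W)
  if (ncol(params$E) > 0) {
    ext <- as.matrix(external_at_t)
    if (nrow(ext) != n) stop("external_at_t not aligned with nucleus row")
    u <- u + ext %*% t(params$E)
  }
  u <- sweep(u, 2, params$h, "+")
  production <- if (phase == "interphase") {
    sweep(regulation_expression(u), 2, params$R, "*")
  } else 0
  D <- diffusion_coefficient(params, row$cycle_index)
  up <- state[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- state[c(seq_len(n)[-1L], n), , drop = FALSE]
  laplacian <- sweep(up + dn - 2 * state, 2, D, "*")
  production + laplacian - sweep(state, 2, params$lambda, "*")
}
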