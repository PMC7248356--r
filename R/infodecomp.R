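#' Four-way joint probability mass function
#'
#' A discretized joint distribution over the driving input (X), the local
#' contextual input (Z), the universal contextual input (U) and the output
#' (Y), stored as a 4-dimensional array. All information quantities in this
#' module are computed in bits (log base 2) with the convention
#' `0 * log 0 = 0`.
#'
#' @param table 4-dimensional non-negative array summing to 1 (within 1e-12),
#'   dimensions ordered (X, Z, U, Y).
#' @param breaks optional list of bin-edge vectors per axis (kept when the
#'   pmf was estimated from samples).
#' @return An object of class `joint_pmf`.
#' @export
joint_pmf <- function(table, breaks = NULL) {
  table <- as.array(table)
  if (length(dim(table)) != 4)
    stop("table must be a 4-dimensional array over (X, Z, U, Y)")
  if (any(table < 0) || any(!is.finite(table)))
    stop("probabilities must be finite and non-negative")
  if (abs(sum(table) - 1) > 1e-12)
    stop("probabilities must sum to 1 (within 1e-12)")
  axes <- c("X", "Z", "U", "Y")
  dimnames(table) <- NULL
  structure(list(table = table, axes = axes, breaks = breaks),
            class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat("Joint pmf over (X, Z, U, Y) with bins",
      paste(dim(x$table), collapse = " x "), "\n")
  invisible(x)
}

axis_index <- function(pmf, axes) {
  if (length(axes) == 0) stop("empty axis set")
  idx <- match(axes, pmf$axes)
  if (any(is.na(idx))) stop("unknown axis: ", paste(axes[is.na(idx)],
                                                    collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicated axis")
  idx
}

marginal_table <- function(pmf, axes) {
  idx <- sort(axis_index(pmf, axes))
  apply(pmf$table, idx, sum)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a marginal, in bits
#'
#' @param pmf a [joint_pmf()].
#' @param axes character subset of `c("X", "Z", "U", "Y")`.
#' @return Entropy in bits.
#' @export
#' @examples
#' p <- array(0, c(2, 1, 1, 2)); p[1, 1, 1, 1] <- p[2, 1, 1, 2] <- 0.5
#' entropy(joint_pmf(p), "Y")  # 1 bit
entropy <- function(pmf, axes) {
  stopifnot(inherits(pmf, "joint_pmf"))
  shannon(marginal_table(pmf, axes))
}

#' Conditional entropy H(target | given), in bits
#'
#' Computed through the chain rule `H(T | G) = H(T, G) - H(G)`.
#'
#' @param pmf a [joint_pmf()].
#' @param target_axes,given_axes disjoint axis sets; `given_axes` may be
#'   empty, in which case the plain entropy is returned.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(pmf, target_axes, given_axes = character()) {
  if (length(intersect(target_axes, given_axes)))
    stop("overlapping axis sets")
  if (length(given_axes) == 0) return(entropy(pmf, target_axes))
  entropy(pmf, c(target_axes, given_axes)) - entropy(pmf, given_axes)
}

#' Mutual information I(A; B), in bits
#'
#' `I(A; B) = H(A) - H(A | B)`; symmetric in its arguments.
#'
#' @param pmf a [joint_pmf()].
#' @param axes_a,axes_b disjoint axis sets.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(pmf, axes_a, axes_b) {
  if (length(intersect(axes_a, axes_b))) stop("overlapping axis sets")
  entropy(pmf, axes_a) - conditional_entropy(pmf, axes_a, axes_b)
}

#' Conditional mutual information I(A; B | C), in bits
#'
#' `I(A; B | C) = H(B | C) - H(B | A, C)`; non-negative for exact pmfs.
#'
#' @param pmf a [joint_pmf()].
#' @param axes_a,axes_b,given_axes pairwise disjoint axis sets.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(pmf, axes_a, axes_b,
                                           given_axes = character()) {
  sets <- list(axes_a, axes_b, given_axes)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("overlapping axis sets")
  conditional_entropy(pmf, axes_b, given_axes) -
    conditional_entropy(pmf, axes_b, c(axes_a, given_axes))
}

#' Four-way interaction information, in bits
#'
#' The signed four-variable interaction term, canonically computed as
#' `I(X; Y) - I(X; Y | Z, U)`. Positive values indicate redundancy among the
#' variables, negative values synergy (e.g. a parity/XOR relation). The
#' other four pair-anchored expressions of the same form are evaluated as
#' diagnostics: they coincide for some distributions but not in general, and
#' the maximum pairwise discrepancy is reported rather than assumed zero.
#'
#' @param pmf a [joint_pmf()] over all four axes.
#' @return List with `value` (bits), `expressions` (all five pair-anchored
#'   evaluations) and `max_discrepancy`.
#' @export
four_way_interaction <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf"))
  pairs <- list(c("X", "Y"), c("X", "Z"), c("X", "U"),
                c("Y", "Z"), c("Y", "U"))
  vals <- vapply(pairs, function(p) {
    rest <- setdiff(pmf$axes, p)
    mutual_information(pmf, p[1], p[2]) -
      conditional_mutual_information(pmf, p[1], p[2], rest)
  }, numeric(1))
  names(vals) <- vapply(pairs, paste, "", collapse = ";")
  list(value = unname(vals[1]), expressions = vals,
       max_discrepancy = max(stats::dist(vals)))
}

#' Weights of the infomax-style objective
#'
#' @param phi0,phi1,phi2,phi3,phi4 reals in `[-1, 1]` weighting, in order:
#'   the four-way interaction term, I(Y;X|Z,U), I(Y;Z|X,U), I(Y;U|X,Z) and
#'   H(Y|X,Z,U).
#' @return An object of class `objective_weights`.
#' @export
objective_weights <- function(phi0 = 1, phi1 = 1, phi2 = 1, phi3 = 1,
                              phi4 = 0) {
  phis <- c(phi0 = phi0, phi1 = phi1, phi2 = phi2, phi3 = phi3, phi4 = phi4)
  if (any(!is.finite(phis)) || any(abs(phis) > 1))
    stop("objective weights must lie in [-1, 1]")
  structure(as.list(phis), class = "objective_weights")
}

#' Decompose the output entropy into contextual information terms
#'
#' Splits `H(Y)` into the four-way interaction term plus the three
#' conditional mutual informations of the output with each input field plus
#' the residual output entropy `H(Y|X,Z,U)`:
#' `H(Y) = I4 + I(Y;X|Z,U) + I(Y;Z|X,U) + I(Y;U|X,Z) + H(Y|X,Z,U) + residual`.
#' The decomposition is exact only up to a residual, which equals
#' `I(Y;Z|X) - I(Y;Z|X,U)` analytically and is reported as a diagnostic.
#' The weighted objective
#' `F = phi0*I4 + phi1*I(Y;X|Z,U) + phi2*I(Y;Z|X,U) + phi3*I(Y;U|X,Z) +
#' phi4*H(Y|X,Z,U)` is evaluated under the supplied weights; with
#' `phi0 = phi1 = 1` and the rest zero it reduces to `I(Y;X)`, and likewise
#' for the other single-field cases.
#'
#' @param pmf a [joint_pmf()] over all four axes.
#' @param phis an [objective_weights()].
#' @return An object of class `decomposition_report`.
#' @export
decompose_output_entropy <- function(pmf, phis = objective_weights()) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (!inherits(phis, "objective_weights"))
    stop("phis must be an objective_weights object")
  I4 <- mutual_information(pmf, "Y", "X") -
    conditional_mutual_information(pmf, "Y", "X", c("Z", "U"))
  I_yx <- conditional_mutual_information(pmf, "X", "Y", c("Z", "U"))
  I_yz <- conditional_mutual_information(pmf, "Z", "Y", c("X", "U"))
  I_yu <- conditional_mutual_information(pmf, "U", "Y", c("X", "Z"))
  H_res <- conditional_entropy(pmf, "Y", c("X", "Z", "U"))
  H_y <- entropy(pmf, "Y")
  residual <- H_y - (I4 + I_yx + I_yz + I_yu + H_res)
  F_val <- phis$phi0 * I4 + phis$phi1 * I_yx + phis$phi2 * I_yz +
    phis$phi3 * I_yu + phis$phi4 * H_res
  structure(list(I4 = I4, I_yx_given_zu = I_yx, I_yz_given_xu = I_yz,
                 I_yu_given_xz = I_yu, H_y_given_xzu = H_res, H_y = H_y,
                 residual = residual, F = F_val, phis = phis),
            class = "decomposition_report")
}

#' @export
print.decomposition_report <- function(x, ...) {
  cat("Output-entropy decomposition (bits)\n")
  terms <- c("I(Y;X;Z;U)" = x$I4, "I(Y;X|Z,U)" = x$I_yx_given_zu,
             "I(Y;Z|X,U)" = x$I_yz_given_xu, "I(Y;U|X,Z)" = x$I_yu_given_xz,
             "H(Y|X,Z,U)" = x$H_y_given_xzu, "H(Y)" = x$H_y,
             "residual" = x$residual, "F" = x$F)
  print(round(terms, 6))
  invisible(x)
}

#' Coerce a decomposition report to a one-row data frame
#'
#' @param x a `decomposition_report`.
#' @param ... unused.
#' @return A one-row `data.frame` of the decomposition terms.
#' @export
as.data.frame.decomposition_report <- function(x, ...) {
  data.frame(I4 = x$I4, I_yx_given_zu = x$I_yx_given_zu,
             I_yz_given_xu = x$I_yz_given_xu,
             I_yu_given_xz = x$I_yu_given_xz,
             H_y_given_xzu = x$H_y_given_xzu, H_y = x$H_y,
             residual = x$residual, F_objective = x$F)
}

#' Plug-in estimation of the four-way pmf from samples
#'
#' Equal-width binning of each column over its observed range, then a
#' normalized 4-way histogram. A constant column collapses to a single
#' degenerate bin.
#'
#' @param samples data frame or matrix with (at least) columns `X`, `Z`,
#'   `U`, `Y`; unnamed input is taken in that order.
#' @param n_bins number of equal-width bins per non-constant axis (>= 2).
#' @return A [joint_pmf()] with bin edges recorded.
#' @export
estimate_pmf <- function(samples, n_bins = 8) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0) stop("zero samples")
  stopifnot(n_bins >= 2)
  axes <- c("X", "Z", "U", "Y")
  if (!all(axes %in% names(samples))) {
    if (ncol(samples) < 4) stop("need columns X, Z, U, Y")
    names(samples)[1:4] <- axes
  }
  bins <- list()
  breaks <- list()
  for (a in axes) {
    v <- samples[[a]]
    if (any(!is.finite(v))) stop("non-finite values in column ", a)
    lo <- min(v); hi <- max(v)
    if (lo == hi) {
      breaks[[a]] <- c(lo, hi)
      bins[[a]] <- rep(1L, length(v))
    } else {
      br <- seq(lo, hi, length.out = n_bins + 1)
      breaks[[a]] <- br
      bins[[a]] <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE),
                             1L), n_bins)
    }
  }
  dims <- unname(vapply(breaks, function(b) max(1L, length(b) - 1L),
                        integer(1)))
  lin <- 1L + (bins$X - 1L) + dims[1] * ((bins$Z - 1L) +
    dims[2] * ((bins$U - 1L) + dims[3] * (bins$Y - 1L)))
  tab <- array(tabulate(lin, nbins = prod(dims)), dims)
  joint_pmf(tab / sum(tab), breaks = breaks)
}

#' Write / read a pmf as dense CSV
#'
#' One row per cell: the four bin indices plus the probability.
#'
#' @param pmf a [joint_pmf()].
#' @param path file path.
#' @return `path` invisibly / a `joint_pmf`.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "joint_pmf"))
  d <- dim(pmf$table)
  grid <- expand.grid(X = seq_len(d[1]), Z = seq_len(d[2]),
                      U = seq_len(d[3]), Y = seq_len(d[4]))
  grid$probability <- as.vector(pmf$table)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  grid <- utils::read.csv(path)
  d <- c(max(grid$X), max(grid$Z), max(grid$U), max(grid$Y))
  tab <- array(0, d)
  tab[cbind(grid$X, grid$Z, grid$U, grid$Y)] <- grid$probability
  joint_pmf(tab)
}
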