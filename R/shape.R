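#' Drop the zero modes of a closed-surface spectrum
#'
#' For a closed surface the constant eigenfunction contributes a zero
#' eigenvalue (one per connected component), which carries no shape
#' information and is removed before the descriptor is built. A mode is
#' treated as zero when `|lambda| < 1e-8 * lambda_{M/2}`.
#'
#' @param spec an [compute_spectrum()] result or numeric eigenvalue vector.
#' @return Numeric vector of nonzero eigenvalues, ascending.
#' @export
drop_zero_modes <- function(spec) {
  vals <- if (inherits(spec, "lb_spectrum")) spec$eigenvalues else
    as.numeric(spec)
  ref <- vals[max(1L, ceiling(length(vals) / 2))]
  vals[abs(vals) >= 1e-8 * ref]
}

#' Re-weight Laplace-Beltrami eigenvalues
#'
#' Laplace eigenvalues of a 2D surface grow linearly with their index
#' (Weyl's law) and their variance grows quadratically, so unweighted high
#' modes would dominate the phenotypic covariance. Dividing the m-th
#' nonzero eigenvalue by its index, `lambda_m / m`, balances the
#' contribution of lower and higher modes.
#'
#' @param values ascending nonnegative eigenvalues with zero modes already
#'   removed (see [drop_zero_modes()]); an `lb_spectrum` is accepted and
#'   has its zero modes dropped first.
#' @return Vector of re-weighted eigenvalues, same length as the input.
#' @export
reweight_eigenvalues <- function(values) {
  if (inherits(values, "lb_spectrum")) values <- drop_zero_modes(values)
  values <- as.numeric(values)
  if (any(values < 0)) stop("eigenvalues must be nonnegative")
  values / seq_along(values)
}

#' Normalize a shape descriptor for the size of the structure
#'
#' Scaling a surface by `s` multiplies every Laplace eigenvalue by
#' `1/s^2`; equivalently, multiplying the eigenvalues by `eta` rescales the
#' underlying manifold by `eta^{-1/2}`. Multiplying by `V^{2/3}` therefore
#' maps every subject to a unit-volume copy of its structure, so that the
#' descriptor measures shape over and above size.
#'
#' @param values numeric vector of (re-weighted) eigenvalues.
#' @param volume enclosed volume of the structure, in mm^3, positive.
#' @return The volume-normalized values.
#' @export
volume_normalize <- function(values, volume) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  as.numeric(values) * volume^(2 / 3)
}

#' Shape descriptor of a single structure
#'
#' Full single-structure pipeline: geometric smoothing, truncated
#' Laplace-Beltrami spectrum, zero-mode removal, index re-weighting and
#' unit-volume normalization.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param n_modes number of nonzero eigenvalues kept in the descriptor
#'   (default 50).
#' @param smooth_iterations geometric smoothing iterations before the
#'   spectrum is computed (default 3).
#' @param structure_name optional label.
#' @param lumped passed to [compute_spectrum()].
#' @return Object of class `shape_descriptor` with `values` (length
#'   `n_modes`), `structure_name` and `volume` (of the smoothed mesh, mm^3).
#' @export
shape_descriptor <- function(mesh, n_modes = 50L, smooth_iterations = 3L,
                             structure_name = "structure", lumped = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  sm <- smooth_mesh(mesh, iterations = smooth_iterations)
  # one extra mode per connected component is consumed by the zero mode
  spec <- compute_spectrum(sm, n_modes = n_modes + 1L, lumped = lumped)
  vals <- drop_zero_modes(spec)
  if (length(vals) < n_modes)
    stop("fewer than ", n_modes, " nonzero modes available; the surface ",
         "may have several connected components")
  vals <- vals[seq_len(n_modes)]
  vol <- spec$enclosed_volume
  if (!is.finite(vol) || vol <= 0)
    stop("enclosed volume unavailable: mesh must be closed and outward-wound")
  values <- volume_normalize(reweight_eigenvalues(vals), vol)
  structure(list(values = values, structure_name = structure_name,
                 volume = vol),
            class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat("shape_descriptor [", x$structure_name, "]: ", length(x$values),
      " components, volume ", signif(x$volume, 5), "\n", sep = "")
  invisible(x)
}

#' Assemble the trait vector for a (possibly bilateral) structure
#'
#' Bilateral structures are analysed as one trait by concatenating the
#' left and right descriptors and averaging the two volumes into a single
#' volume covariate. Unilateral structures pass through unchanged.
#'
#' @param left a [shape_descriptor()].
#' @param right optional [shape_descriptor()] for the contralateral
#'   structure; `NULL` for unilateral structures.
#' @return List with `trait` (length M or 2M) and `volume_covariate`.
#' @export
assemble_descriptor <- function(left, right = NULL) {
  stopifnot(inherits(left, "shape_descriptor"))
  if (is.null(right))
    return(list(trait = left$values, volume_covariate = left$volume))
  stopifnot(inherits(right, "shape_descriptor"))
  if (length(left$values) != length(right$values))
    stop("left and right descriptors have different lengths")
  list(trait = c(left$values, right$values),
       volume_covariate = mean(c(left$volume, right$volume)))
}
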