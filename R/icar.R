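#' Scaled ICAR precision structure for an area graph
#'
#' Builds the intrinsic conditional autoregressive (ICAR) structure underlying
#' the spatially structured half of the BYM2 model. The precision structure is
#' the graph Laplacian `Q = D - A`; because `Q` is singular (one null vector
#' per connected component) the field is defined under a sum-to-zero
#' constraint within each component. Each component is then *scaled*: the
#' scaling factor is the geometric mean of the marginal variances of the
#' constrained field (diagonal of the constrained generalised inverse of the
#' component's Laplacian), so that after scaling the structured field has unit
#' geometric-mean marginal variance and `sigma` in the BYM2 model is
#' interpretable as the marginal standard deviation of the combined effect
#' regardless of graph topology.
#'
#' Single-node components ("islands") carry no structured effect and are
#' excluded from scaling; in [fit_bym2()] they receive a purely unstructured
#' effect.
#'
#' @param graph An [area_graph].
#' @return An object of class `scaled_icar`: list with the Laplacian `Q`
#'   (dense matrix), `components` (per component: `idx`, eigen `values` /
#'   `vectors` of the component Laplacian restricted to its non-null space,
#'   `scaling` factor, `marginal_var` after scaling), `scaling` (per-area
#'   scaling factor, `NA` for islands), and `island` (logical per area).
#' @examples
#' g <- simulate_area_graph(9, "lattice", seed = 1)
#' s <- scaled_icar(g)
#' exp(mean(log(s$components[[1]]$marginal_var)))  # 1 by construction
#' @export
scaled_icar <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- n_areas(graph)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, graph$neighbours[[i]]] <- 1
  Q <- diag(lengths(graph$neighbours)) - A
  scaling <- rep(NA_real_, n)
  island <- lengths(graph$neighbours) == 0L
  comps <- list()
  for (k in seq_len(graph$n_components)) {
    idx <- which(graph$component == k)
    m <- length(idx)
    if (m == 1L) {
      comps[[k]] <- list(idx = idx, values = numeric(0),
                         vectors = matrix(0, 1, 0), scaling = NA_real_,
                         marginal_var = NA_real_)
      next
    }
    eg <- eigen(Q[idx, idx, drop = FALSE], symmetric = TRUE)
    keep <- seq_len(m - 1L)            # drop the single null eigenvalue
    vals <- eg$values[keep]
    vecs <- eg$vectors[, keep, drop = FALSE]
    # constrained generalised inverse diagonal: sum_k v_ik^2 / lambda_k
    gvar <- rowSums(sweep(vecs^2, 2, vals, "/"))
    s <- exp(mean(log(gvar)))
    comps[[k]] <- list(idx = idx, values = vals, vectors = vecs,
                       scaling = s, marginal_var = gvar / s)
    scaling[idx] <- s
  }
  structure(list(Q = Q, components = comps, scaling = scaling,
                 island = island),
            class = "scaled_icar")
}

#' @export
print.scaled_icar <- function(x, ...) {
  cat("<scaled_icar> ", nrow(x$Q), " areas, ", length(x$components),
      " component(s), ", sum(x$island), " island(s)\n", sep = "")
  for (cmp in x$components) {
    if (length(cmp$idx) > 1L) {
      cat("  component of ", length(cmp$idx), " areas: scaling factor ",
          format(cmp$scaling, digits = 6), "\n", sep = "")
    }
  }
  invisible(x)
}
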