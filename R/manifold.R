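# Constant-curvature model spaces and Riemannian stochastic gradient descent
# embedding. Spaces are kept at unit curvature; a jointly optimized global
# scale absorbs curvature magnitude. Hyperbolic space uses the hyperboloid
# (Minkowski) model internally for stable gradients.

#' Specify a constant-curvature model space
#'
#' @param curvature `"euclidean"`, `"hyperbolic"` or `"spherical"` (zero,
#'   negative, positive curvature). The circle S1 is `manifold_spec("spherical", 1)`.
#' @param dim intrinsic dimension, >= 1.
#' @return an object of class `manifold_spec`.
#' @export
manifold_spec <- function(curvature = c("euclidean", "hyperbolic", "spherical"),
                          dim = 2L) {
  curvature <- match.arg(curvature)
  dim <- assert_count(dim, "dim", min = 1L)
  structure(list(curvature = curvature, dim = dim), class = "manifold_spec")
}

#' Parse a compact space label such as "H2", "E10" or "S1"
#'
#' @param label string: E/H/S followed by the dimension.
#' @return a [manifold_spec()].
#' @export
parse_manifold <- function(label) {
  m <- regmatches(label, regexec("^([EHS])([0-9]+)$", label))[[1L]]
  if (length(m) != 3L)
    stop_hc("cannot parse space label '", label, "' (expected e.g. H2, E10, S1)")
  manifold_spec(switch(m[2L], E = "euclidean", H = "hyperbolic",
                       S = "spherical"),
                as.integer(m[3L]))
}

#' @export
print.manifold_spec <- function(x, ...) {
  cat(sprintf("<manifold_spec> %s, dim %d\n", x$curvature, x$dim))
  invisible(x)
}

ambient_dim <- function(m) {
  if (m$curvature == "euclidean") m$dim else m$dim + 1L
}

# Minkowski bilinear form with time-like first coordinate.
minkowski <- function(p, q) -p[1L] * q[1L] + sum(p[-1L] * q[-1L])

# residual of the model-space constraint at a point
constraint_residual <- function(p, m) {
  switch(m$curvature,
         euclidean = 0,
         spherical = abs(sum(p^2) - 1),
         hyperbolic = abs(minkowski(p, p) + 1))
}

# project a point back onto the model space (exactly, up to rounding)
retract_point <- function(p, m) {
  switch(m$curvature,
         euclidean = p,
         spherical = p / sqrt(sum(p^2)),
         hyperbolic = c(sqrt(1 + sum(p[-1L]^2)), p[-1L]))
}

#' Geodesic distance between two points of a model space
#'
#' Euclidean norm for zero curvature, `acos` of the dot product on the unit
#' sphere, `acosh` of minus the Minkowski product on the unit hyperboloid.
#'
#' @param p,q points (numeric vectors of the ambient dimension: `dim` for
#'   Euclidean space, `dim + 1` otherwise).
#' @param m a [manifold_spec()].
#' @param tol allowed model-space constraint violation.
#' @return nonnegative scalar.
#' @export
space_distance <- function(p, q, m, tol = 1e-6) {
  if (length(p) != ambient_dim(m) || length(q) != ambient_dim(m))
    stop_hc("points must have ambient dimension ", ambient_dim(m))
  if (constraint_residual(p, m) > tol || constraint_residual(q, m) > tol)
    stop_hc("point does not satisfy the ", m$curvature,
            " model-space constraint", class = "hypercon_invalid_point")
  switch(m$curvature,
         euclidean = sqrt(sum((p - q)^2)),
         spherical = acos(min(1, max(-1, sum(p * q)))),
         hyperbolic = acosh(max(1, -minkowski(p, q))))
}

# Pairwise geodesic distances between rows of a coordinate matrix.
manifold_distances <- function(x, m) {
  switch(m$curvature,
         euclidean = as.matrix(stats::dist(x)),
         spherical = {
           gram <- pmin(pmax(tcrossprod(x), -1), 1)
           d <- acos(gram); diag(d) <- 0; d
         },
         hyperbolic = {
           gram <- tcrossprod(x[, -1L, drop = FALSE]) -
             tcrossprod(x[, 1L, drop = FALSE])
           d <- acosh(pmax(-gram, 1)); diag(d) <- 0; d
         })
}

# weighted median (lower weighted median), used for the distortion-optimal
# global scale
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

# distortion minimized over a global scale of the embedded distances:
# min_s mean(|dV/s - dU|/dU); in u = 1/s this is a weighted-median problem.
scaled_distortion <- function(dv, du) {
  r <- dv / du
  u <- weighted_median(1 / r[r > 0], r[r > 0])
  list(d_avg = mean(abs(r * u - 1)), scale = 1 / u)
}

#' Embed a connected graph into a constant-curvature space by RSGD
#'
#' Minimizes the distortion-style loss
#' `L = sum_pairs ((d_V / (s d_U))^2 - 1)^2` over node coordinates on the
#' model space, with the global scale `s` re-optimized in closed form every
#' epoch. Each step computes the ambient Euclidean gradient, applies the
#' Riemannian correction and tangent-space projection, and retracts by the
#' exponential map; coordinates are re-projected onto the model space after
#' each update. Convergence is declared when the relative loss change over
#' the last 10 epochs falls below `tol`.
#'
#' @param g connected [binary_graph()] or igraph.
#' @param m a [manifold_spec()] or compact label (`"H2"`, `"E10"`, ...).
#' @param epochs maximum epochs (>= 1; default 2000, capped at 3000).
#' @param lr learning rate.
#' @param batch node pairs per gradient step; `Inf` (default) is full batch.
#' @param seed integer seed for initialization and batch shuffling.
#' @param tol relative loss-change convergence tolerance.
#' @return an `embedding_result`: `coordinates` (n x ambient matrix),
#'   `loss_trace`, `converged`, `epochs_run`, `d_avg` (scale-optimized
#'   distortion), `map_score`, `scale`, `space`.
#' @export
rsgd_embed <- function(g, m, epochs = 2000L, lr = 0.1, batch = Inf,
                       seed = 1L, tol = 1e-4) {
  if (is.character(m)) m <- parse_manifold(m)
  epochs <- assert_count(epochs, "epochs", min = 1L)
  epochs <- min(epochs, 3000L)
  du <- graph_metric(g)           # errors on disconnected input
  n <- nrow(du)
  adim <- ambient_dim(m)
  pr <- upper_pairs(n)
  du_p <- du[pr]

  # Unit-scale tangent noise around the pole/origin: with the global scale
  # optimized jointly, a near-zero initialization would confine the whole
  # optimization to the flat small-distance regime where curvature never
  # engages, so the starting spread must be of order one.
  state <- with_seed(seed, {
    x <- matrix(stats::rnorm(n * adim, sd = 0.5), n, adim)
    if (m$curvature != "euclidean") {
      x[, 1L] <- 1          # near the pole / hyperboloid origin
      x <- t(apply(x, 1L, retract_point, m = m))
    }
    list(x = x, shuffle_seeds = sample.int(1e6, epochs))
  })
  x <- state$x

  loss_of <- function(x) {
    dv <- manifold_distances(x, m)[pr]
    r2 <- (dv / du_p)^2
    u <- sum(r2) / max(sum(r2^2), 1e-300)   # optimal 1/s^2
    list(loss = sum((r2 * u - 1)^2), u = u, dv = dv)
  }

  loss_trace <- numeric(0)
  converged <- FALSE
  cur_lr <- lr
  n_pairs <- nrow(pr)
  bsize <- if (!is.finite(batch)) n_pairs else max(1L, as.integer(batch))

  for (ep in seq_len(epochs)) {
    full <- loss_of(x)
    loss_trace[ep] <- full$loss
    if (ep > 10L) {
      recent <- loss_trace[(ep - 10L):ep]
      if (max(recent) - min(recent) <= tol * max(abs(recent[1L]), 1e-12)) {
        converged <- TRUE
        break
      }
    }
    u <- full$u
    # exponentially decaying step size (to 1% of lr by the last epoch); the
    # step itself is normalized inside rsgd_step so progress is proportional
    # to the configuration's current scale
    step_ep <- cur_lr * 0.01^(ep / epochs)
    ord <- if (bsize < n_pairs)
      with_seed(state$shuffle_seeds[ep], sample.int(n_pairs)) else
        seq_len(n_pairs)
    for (start in seq(1L, n_pairs, by = bsize)) {
      sel <- ord[start:min(start + bsize - 1L, n_pairs)]
      x <- rsgd_step(x, m, pr[sel, , drop = FALSE], du_p[sel], u, step_ep)
      if (any(!is.finite(x))) {
        # overflow: retry once from scratch with a smaller step
        if (cur_lr < lr) stop_hc("RSGD diverged on the ", m$curvature,
                                 " model even after step-size reduction")
        cur_lr <- lr / 10
        x <- state$x
        break
      }
    }
  }

  dv_full <- manifold_distances(x, m)
  sd_ <- scaled_distortion(dv_full[pr], du_p)
  structure(list(
    coordinates = x, loss_trace = loss_trace, converged = converged,
    epochs_run = length(loss_trace), d_avg = sd_$d_avg,
    map_score = mean_average_precision(g, dv_full),
    scale = sd_$scale, space = m), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "<embedding_result> %s%d: d_avg = %.4f, mAP = %.4f, %s in %d epochs\n",
    toupper(substr(x$space$curvature, 1, 1)), x$space$dim, x$d_avg,
    x$map_score, if (x$converged) "converged" else "not converged",
    x$epochs_run))
  invisible(x)
}

# One RSGD step over the given pairs: ambient gradient of the loss,
# Riemannian correction + tangent projection, exponential-map retraction.
rsgd_step <- function(x, m, pairs, du_p, u, step) {
  n <- nrow(x)
  grad <- matrix(0, n, ncol(x))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  xi <- x[i, , drop = FALSE]; xj <- x[j, , drop = FALSE]

  if (m$curvature == "euclidean") {
    diff <- xi - xj
    dv <- sqrt(rowSums(diff^2))
    gd <- loss_dgrad(dv, du_p, u)
    co <- gd / pmax(dv, 1e-12)
    gi <- diff * co
    gj <- -gi
  } else if (m$curvature == "spherical") {
    c_ <- pmin(1, pmax(-1, rowSums(xi * xj)))
    dv <- acos(c_)
    gd <- loss_dgrad(dv, du_p, u)
    co <- -gd / sqrt(pmax(1 - c_^2, 1e-12))
    gi <- xj * co
    gj <- xi * co
  } else {
    b <- pmax(1 + 1e-15,
              xi[, 1L] * xj[, 1L] -
                rowSums(xi[, -1L, drop = FALSE] * xj[, -1L, drop = FALSE]))
    dv <- acosh(b)
    gd <- loss_dgrad(dv, du_p, u)
    co <- gd / sqrt(pmax(b^2 - 1, 1e-12))
    # ambient gradient (-J q) followed by the Riemannian correction J gives -q
    gi <- -xj * co
    gj <- -xi * co
  }
  for (k in seq_along(i)) {
    grad[i[k], ] <- grad[i[k], ] + gi[k, ]
    grad[j[k], ] <- grad[j[k], ] + gj[k, ]
  }

  # normalize: the loss is (nearly) scale-free, so raw gradients scale
  # inversely with the configuration's size; steps are made proportional to
  # the current characteristic distance instead
  char <- stats::median(dv)
  gnorm <- sqrt(mean(rowSums(grad^2)))
  if (!is.finite(gnorm) || gnorm < 1e-300) return(x)
  step <- step * max(char, 1e-12) / gnorm

  for (v in seq_len(n)) {
    gv <- grad[v, ]
    if (!any(gv != 0)) next
    p <- x[v, ]
    if (m$curvature == "euclidean") {
      x[v, ] <- p - step * gv
      next
    }
    if (m$curvature == "spherical") {
      tv <- -(gv - sum(gv * p) * p) * step
      tn <- sqrt(sum(tv^2))
      tn <- min(tn, 1)                     # trust region
      if (tn > 1e-15) {
        dirv <- tv / sqrt(sum(tv^2))
        x[v, ] <- retract_point(cos(tn) * p + sin(tn) * dirv, m)
      }
    } else {
      tv <- gv + minkowski(p, gv) * p      # tangent projection (post-correction)
      tv <- -tv * step
      tn2 <- minkowski(tv, tv)
      if (tn2 > 1e-30) {
        tn <- min(sqrt(tn2), 1)
        dirv <- tv / sqrt(tn2)
        x[v, ] <- retract_point(cosh(tn) * p + sinh(tn) * dirv, m)
      }
    }
  }
  x
}

# dL/d(dV) for the pairwise loss ((dV^2 u / dU^2) - 1)^2 with u = 1/s^2
loss_dgrad <- function(dv, du_p, u) {
  a <- u / du_p^2
  4 * a * dv * (a * dv^2 - 1)
}
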