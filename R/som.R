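# Self-organizing map clustering of rigid-body poses.  A pose is reduced
# to a 7-dimensional descriptor -- the mobile body's center of mass in the
# fixed body's reference frame (3) plus the unit quaternion of its
# rotation relative to the mobile template (4) -- and compared with the
# mixed metric
#
#   d(n, m) = ||com_n - com_m|| + (2 dmax / pi) * arccos |<quat_n, quat_m>|,
#
# dmax being the largest space diagonal of the bounding box of the
# training descriptors' centers of mass.  The absolute dot product folds
# the quaternion double cover (q and -q are the same rotation).  Neuron
# updates interpolate linearly in Cartesian space and by sign-aligned
# slerp on the unit 4-sphere.

#' Pose descriptor: center of mass + quaternion in the fixed-body frame
#'
#' Superposes the pose's fixed-body atoms onto the system's fixed-body
#' reference (removing any global rigid motion of the complex), applies
#' the same transform to the mobile body, and returns the mobile center of
#' mass together with the quaternion rotating the mobile template onto the
#' mobile body.
#'
#' @param system a [rigid_system] providing the reference templates.
#' @param xyz pose coordinates (defaults to the system's current ones).
#' @param rmsd_tol maximal fixed-body superposition RMSD before a frame
#'   error (the fixed body must be rigid).
#' @return numeric(7): `(com_x, com_y, com_z, qw, qx, qy, qz)`, unit
#'   quaternion with nonnegative scalar part.
#' @export
make_descriptor <- function(system, xyz = NULL, rmsd_tol = 0.1) {
  if (is.null(xyz)) xyz <- system$mol$xyz
  fx <- xyz[system$fixed, , drop = FALSE]
  fit <- kabsch_fit(fx, system$fixed_ref)
  if (fit$rmsd > rmsd_tol)
    stop("fixed body does not superpose on its reference (RMSD ",
         signif(fit$rmsd, 3), " A)")
  # transform mapping pose -> reference frame: x |-> (x - cp) R + cq
  mb <- sweep(sweep(xyz[system$mobile, , drop = FALSE], 2, fit$center_p) %*%
                fit$R, 2, fit$center_q, `+`)
  com <- colMeans(mb)
  rfit <- kabsch_fit(system$mobile_ref, sweep(mb, 2, com))
  c(com, mat_to_quat(t(rfit$R)))
}

#' Mixed Euclidean/quaternion distance between pose descriptors
#'
#' @param a,b numeric(7) descriptors (unit quaternions in positions 4-7).
#' @param dmax scale of the rotational term: the largest space diagonal of
#'   the bounding box of the training centers of mass.
#' @return nonnegative symmetric distance; 0 iff same com and same
#'   rotation (up to quaternion sign).
#' @export
som_distance <- function(a, b, dmax) {
  stopifnot(dmax > 0)
  dcom <- sqrt(sum((a[1:3] - b[1:3])^2))
  dt <- min(abs(sum(a[4:7] * b[4:7])), 1)
  if (dt > 1 - 1e-12) dt <- 1  # identical rotations: exactly zero arc
  dcom + 2 * dmax / pi * acos(dt)
}

# vectorized descriptor-to-all-neurons distance
dist_to_neurons <- function(d, com, quat, dmax) {
  dcom <- sqrt(rowSums(sweep(com, 2, d[1:3])^2))
  dt <- pmin(abs(drop(quat %*% d[4:7])), 1)
  dt[dt > 1 - 1e-12] <- 1
  dcom + 2 * dmax / pi * acos(dt)
}

#' SOM training configuration
#'
#' @param epochs passes over the training set.
#' @param lr_start,lr_end learning rate, linearly decayed.
#' @param radius_start,radius_end Gaussian neighborhood radius (grid
#'   units), exponentially decayed; `radius_start = NULL` means
#'   `max(shape) / 2`.
#' @param seed RNG seed (initialization and sample order).
#' @return list of class `som_config`.
#' @export
som_config <- function(epochs = 10, lr_start = 0.5, lr_end = 0.01,
                       radius_start = NULL, radius_end = 1, seed = 1) {
  structure(list(epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end, radius_start = radius_start,
                 radius_end = radius_end, seed = as.integer(seed)),
            class = "som_config")
}

#' Train a self-organizing map on pose descriptors
#'
#' Classic online SOM under the mixed metric: per sample, the best-matching
#' unit (BMU) is found with [som_distance()]; every neuron within the
#' Gaussian grid neighborhood moves toward the sample -- centers of mass by
#' linear interpolation, quaternions by sign-aligned spherical
#' interpolation (renormalized after every update).  `dmax` is computed
#' once from the training set and frozen in the map.
#'
#' @param descriptors n x 7 matrix of [make_descriptor()] rows.
#' @param shape integer(2), map rows and columns.
#' @param config a [som_config()].
#' @return object of class `saxs_som`: neuron `com` (k x 3), `quat`
#'   (k x 4), grid coordinates, `hits`, `dmax`, per-epoch mean quantization
#'   error `qe`, and the config.
#' @export
train_som <- function(descriptors, shape = c(15, 15), config = som_config()) {
  descriptors <- as.matrix(descriptors)
  n <- nrow(descriptors)
  if (n == 0) stop("no descriptors to train on")
  k <- prod(shape)
  if (n < k / 10)
    warning("fewer than shape area / 10 samples; map will be sparse")
  box <- apply(descriptors[, 1:3, drop = FALSE], 2, range)
  dmax <- sqrt(sum((box[2, ] - box[1, ])^2))
  if (dmax == 0) dmax <- 1  # degenerate cloud: pure rotational metric scale
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]),
                                col = seq_len(shape[2])))
  r0 <- if (is.null(config$radius_start)) max(shape) / 2 else
    config$radius_start
  with_seed(config$seed, {
    init <- sample.int(n, k, replace = TRUE)
    com <- descriptors[init, 1:3, drop = FALSE]
    quat <- descriptors[init, 4:7, drop = FALSE]
    total <- config$epochs * n
    it <- 0
    qe <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      err <- 0
      for (s in ord) {
        it <- it + 1
        frac <- (it - 1) / max(total - 1, 1)
        lr <- config$lr_start + frac * (config$lr_end - config$lr_start)
        rad <- r0 * (config$radius_end / r0)^frac
        d <- descriptors[s, ]
        dist <- dist_to_neurons(d, com, quat, dmax)
        bmu <- which.min(dist)
        err <- err + dist[bmu]
        gd2 <- (grid[, 1] - grid[bmu, 1])^2 + (grid[, 2] - grid[bmu, 2])^2
        h <- lr * exp(-gd2 / (2 * rad^2))
        upd <- which(h > 1e-4)
        com[upd, ] <- com[upd, , drop = FALSE] +
          h[upd] * (matrix(d[1:3], length(upd), 3, byrow = TRUE) -
                      com[upd, , drop = FALSE])
        for (u in upd)
          quat[u, ] <- quat_slerp(quat[u, ], d[4:7], min(h[u], 1))
      }
      qe[ep] <- err / n
    }
    som <- structure(list(shape = shape, grid = grid, com = com, quat = quat,
                          dmax = dmax, qe = qe, config = config,
                          hits = integer(k)),
                     class = "saxs_som")
    som$hits <- tabulate(som_assign(som, descriptors), nbins = k)
    som
  })
}

#' Best-matching unit of each descriptor
#'
#' @param som a trained [train_som()] map.
#' @param descriptors n x 7 matrix.
#' @return integer vector of neuron indices (row-major over the grid).
#' @export
som_assign <- function(som, descriptors) {
  descriptors <- as.matrix(descriptors)
  vapply(seq_len(nrow(descriptors)), function(i) {
    which.min(dist_to_neurons(descriptors[i, ], som$com, som$quat, som$dmax))
  }, integer(1))
}

#' Project a per-structure property onto the map
#'
#' Assigns each descriptor to its BMU and reduces the associated values
#' per neuron; neurons with no assigned structure are `NA` (empty).
#'
#' @param som a trained map.
#' @param descriptors n x 7 matrix.
#' @param values one value per descriptor (e.g. chi-square).
#' @param reducer `"min"` or `"mean"`.
#' @return list: `value` (per-neuron aggregate, `NA` where empty), `hits`
#'   (per-neuron count), `matrix` (the aggregate shaped as the grid).
#' @export
som_project <- function(som, descriptors, values,
                        reducer = c("min", "mean")) {
  reducer <- match.arg(reducer)
  descriptors <- as.matrix(descriptors)
  if (length(values) != nrow(descriptors))
    stop("one value per descriptor required")
  bmu <- som_assign(som, descriptors)
  k <- prod(som$shape)
  out <- rep(NA_real_, k)
  agg <- tapply(values, bmu, if (reducer == "min") min else mean)
  out[as.integer(names(agg))] <- agg
  list(value = out, hits = tabulate(bmu, nbins = k),
       matrix = matrix(out, som$shape[1], som$shape[2]))
}

#' Rebuild a 3D pose from a neuron (or any descriptor)
#'
#' Places the mobile template rotated by the descriptor's quaternion with
#' its center of mass at the descriptor's com, the fixed template at its
#' reference position, and flags steric clash.
#'
#' @param descriptor numeric(7) (a neuron's `c(com, quat)` row or a
#'   [make_descriptor()] output).
#' @param system the [rigid_system] providing the templates.
#' @return list: `mol` (a [saxs_molecule] of the two bodies), `clash`
#'   (logical; `TRUE` if the excluded-volume penalty is positive).
#' @export
reconstruct_pose <- function(descriptor, system) {
  q <- quat_normalize(descriptor[4:7])
  mol <- system$mol
  xyz <- mol$xyz
  xyz[system$fixed, ] <- system$fixed_ref
  xyz[system$mobile, ] <- sweep(system$mobile_ref %*% t(quat_to_mat(q)), 2,
                                descriptor[1:3], `+`)
  keep <- c(system$fixed, system$mobile)
  out <- subset_molecule(mol, keep)
  out$xyz <- xyz[keep, , drop = FALSE]
  list(mol = out, clash = excluded_volume(out) > 0)
}

#' Group non-empty neurons by connected components
#'
#' Labels non-empty neurons by connected-component search over
#' grid-adjacent (4-neighborhood) neurons whose descriptor distance is
#' below a threshold -- an automated stand-in for a visual reading of the
#' map's cluster structure.
#'
#' @param som a trained map with `hits` filled.
#' @param threshold [som_distance()] threshold joining adjacent neurons.
#' @return integer vector, one label per neuron (`NA` for empty neurons).
#' @export
som_groups <- function(som, threshold) {
  k <- prod(som$shape)
  lab <- rep(NA_integer_, k)
  nonempty <- which(som$hits > 0)
  nb <- function(i) {
    rc <- som$grid[i, ]
    cand <- which(abs(som$grid[, 1] - rc[1]) + abs(som$grid[, 2] - rc[2]) == 1)
    cand[cand %in% nonempty]
  }
  cur <- 0L
  for (s in nonempty) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in nb(i)) {
        if (is.na(lab[j]) &&
            som_distance(c(som$com[i, ], som$quat[i, ]),
                         c(som$com[j, ], som$quat[j, ]), som$dmax) < threshold) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' @export
print.saxs_som <- function(x, ...) {
  cat(sprintf("SOM %d x %d: %d/%d non-empty neurons, dmax = %.3g A, final QE = %.4g\n",
              x$shape[1], x$shape[2], sum(x$hits > 0), prod(x$shape),
              x$dmax, x$qe[length(x$qe)]))
  invisible(x)
}
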