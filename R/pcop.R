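#' Fit a principal curve of oriented points (PCOP) to a 2-D cloud
#'
#' Summarises a two-dimensional data cloud by a chain of principal oriented
#' points (POPs). Each POP is the local first-principal-direction summary of a
#' neighbourhood: the tracer starts at the data point extreme along the global
#' first principal component, repeatedly takes the neighbourhood of the
#' current position, computes the local principal direction (sign-aligned with
#' the previous one), snaps the position orthogonally onto the local mean, and
#' advances by a fixed step; it stops when no data lie ahead of the current
#' POP. The fit is fully deterministic: no random initialisation.
#'
#' A closed curve (the traversal returns to its start after winding through
#' roughly a full turn) is flagged `closed`.
#'
#' @param points numeric n x 2 matrix of (standardized) observations.
#' @param bandwidth_fraction fraction of the points in each local
#'   neighbourhood (default 0.2).
#' @param step_fraction advance per POP as a fraction of the data diameter
#'   (default 0.05).
#' @param min_neighbourhood minimum neighbourhood size (default 10).
#' @return An object of class `PrincipalCurve`: list with `pops` (m x 2
#'   positions), `directions` (m x 2 unit tangents), `support` (neighbourhood
#'   size), `closed`, `f` (uncorrelation factor, see
#'   [uncorrelation_factor()]), `diameter`, `step`.
#' @export
fit_pcop <- function(points, bandwidth_fraction = 0.2, step_fraction = 0.05,
                     min_neighbourhood = 10) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("points must be an n x 2 matrix", call. = FALSE)
  if (anyNA(points)) stop("points must not contain NA", call. = FALSE)
  n <- nrow(points)
  if (n < 20) stop("insufficient data: need at least 20 points", call. = FALSE)
  diam <- .cloud_diameter(points)
  if (diam < 1e-12) stop("degenerate input: all points identical", call. = FALSE)
  if (bandwidth_fraction <= 0 || bandwidth_fraction > 1)
    stop("bandwidth_fraction must be in (0, 1]", call. = FALSE)
  if (step_fraction <= 0 || step_fraction > 0.5)
    stop("step_fraction must be in (0, 0.5]", call. = FALSE)
  k <- min(n, max(min_neighbourhood, ceiling(bandwidth_fraction * n)))
  step <- step_fraction * diam

  pc1 <- .principal_direction(points)
  # orient toward increasing first coordinate (tie: increasing second)
  if (pc1[1] < 0 || (pc1[1] == 0 && pc1[2] < 0)) pc1 <- -pc1
  proj <- points %*% pc1
  start <- points[which.min(proj), ]

  fwd <- .trace_pcop(points, start, pc1, k, step)
  if (fwd$closed) {
    P <- fwd$P
  } else {
    bwd <- .trace_pcop(points, start, -pc1, k, step)
    P <- rbind(if (nrow(bwd$P) > 1) bwd$P[nrow(bwd$P):2, , drop = FALSE],
               fwd$P)
  }
  # drop consecutive duplicates
  if (nrow(P) > 1) {
    keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] -
                             P[-nrow(P), , drop = FALSE])^2) > 1e-18)
    P <- P[keep, , drop = FALSE]
  }
  if (nrow(P) < 2) {
    # the tracer found no forward structure at all (pathological clouds):
    # emit a minimal segment along the global principal direction so the
    # curve object stays valid; its extent penalty drives f toward 1
    P <- rbind(P[1, ] - (step / 2) * pc1, P[1, ] + (step / 2) * pc1)
  }
  dirs <- .polyline_tangents(P)
  curve <- structure(list(pops = unname(P), directions = dirs, support = k,
                          closed = fwd$closed, f = NA_real_,
                          diameter = diam, step = step),
                     class = "PrincipalCurve")
  curve$f <- uncorrelation_factor(curve, points)
  curve
}

#' @export
print.PrincipalCurve <- function(x, ...) {
  cat(sprintf("PrincipalCurve: %d POPs, %s, f = %.4g\n", nrow(x$pops),
              if (x$closed) "closed" else "open", x$f))
  invisible(x)
}

# max pairwise distance; exact, clouds here are small (samples of a pair)
.cloud_diameter <- function(points) {
  if (nrow(points) > 600) {
    # convex-hull reduction keeps this exact for big clouds
    h <- grDevices::chull(points)
    points <- points[h, , drop = FALSE]
  }
  max(stats::dist(points))
}

.principal_direction <- function(points) {
  cv <- stats::cov(points)
  eigen(cv, symmetric = TRUE)$vectors[, 1]
}

# march POPs from pos0 along dir0 until the data run out (or the curve closes)
.trace_pcop <- function(points, pos0, dir0, k, step) {
  n <- nrow(points)
  maxs <- ceiling(6 / (step / .cloud_diameter_cache(points)))
  maxs <- min(maxs, 500L)
  pops <- matrix(NA_real_, maxs, 2)
  pos <- pos0
  dir <- dir0 / sqrt(sum(dir0^2))
  closed <- FALSE
  went_far <- FALSE
  winding <- 0
  wind_pos <- 0
  wind_neg <- 0
  prev_dir <- NULL
  m <- 0L
  for (i in seq_len(maxs)) {
    d2 <- (points[, 1] - pos[1])^2 + (points[, 2] - pos[2])^2
    ord_nb <- order(d2, method = "radix")[seq_len(k)]
    nb <- points[ord_nb, , drop = FALSE]
    r_k <- sqrt(d2[ord_nb[k]])
    mu <- colMeans(nb)
    lv <- .principal_direction(nb)
    if (sum(lv * dir) < 0) lv <- -lv
    pop <- mu + sum((pos - mu) * lv) * lv
    m <- m + 1L
    pops[m, ] <- pop
    if (!is.null(prev_dir)) {
      cr <- prev_dir[1] * lv[2] - prev_dir[2] * lv[1]
      dt <- max(-1, min(1, sum(prev_dir * lv)))
      turn <- sign(cr) * acos(dt) * 180 / pi
      winding <- winding + turn
      if (turn > 0) wind_pos <- wind_pos + turn else wind_neg <- wind_neg - turn
    }
    prev_dir <- lv
    dir <- lv
    # stop at the data hull: no point lies in the forward corridor (the k-NN
    # radius can be far smaller than the step inside dense clumps, so the
    # test must look at all points)
    corridor <- max(2 * step, r_k)
    tt <- (points[, 1] - pop[1]) * dir[1] + (points[, 2] - pop[2]) * dir[2]
    oo <- abs((points[, 1] - pop[1]) * dir[2] - (points[, 2] - pop[2]) * dir[1])
    if (!any(tt > step / 2 & tt <= step / 2 + corridor & oo <= corridor)) break
    pos <- pop + step * dir
    gap <- sqrt(sum((pos - pops[1, ])^2))
    if (gap > 3 * step) went_far <- TRUE
    # closure: back near the start after about one full turn of consistent
    # sign (a wiggly path through a blob winds with mixed signs)
    if (m >= 5 && went_far && gap < 1.5 * step &&
        abs(winding) > 270 && abs(winding) < 450 &&
        min(wind_pos, wind_neg) < 0.25 * max(wind_pos, wind_neg)) {
      closed <- TRUE
      break
    }
  }
  list(P = pops[seq_len(m), , drop = FALSE], closed = closed)
}

# memo-free helper: diameter needed for the step cap inside the tracer
.cloud_diameter_cache <- function(points) .cloud_diameter(points)

.polyline_tangents <- function(P) {
  m <- nrow(P)
  if (m < 2) return(matrix(c(1, 0), m, 2, byrow = TRUE))
  seg <- diff(P)
  len <- sqrt(rowSums(seg^2))
  len[len == 0] <- 1
  u <- seg / len
  d <- rbind(u[1, , drop = FALSE],
             (u[-nrow(u), , drop = FALSE] + u[-1, , drop = FALSE]) / 2,
             u[nrow(u), , drop = FALSE])
  l2 <- sqrt(rowSums(d^2))
  l2[l2 == 0] <- 1
  d / l2
}

.arc_lengths <- function(P) c(0, cumsum(sqrt(rowSums(diff(P)^2))))

# sum of unsigned direction changes between consecutive polyline segments (deg)
.total_winding <- function(P) {
  if (nrow(P) < 3) return(0)
  seg <- diff(P)
  len <- sqrt(rowSums(seg^2))
  ok <- len > 0
  seg <- seg[ok, , drop = FALSE]
  if (nrow(seg) < 2) return(0)
  u <- seg / sqrt(rowSums(seg^2))
  dt <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  sum(acos(pmax(-1, pmin(1, dt)))) * 180 / pi
}

#' Uncorrelation factor of a fitted curve
#'
#' The uncorrelation factor f in \[0, 1\] measures how badly a curve explains
#' its data cloud: the mean squared orthogonal distance from the points to the
#' polyline, relative to the total dispersion of the cloud, times a morphology
#' penalty that punishes curves whose pattern does not describe the cloud
#' (over-long or repeatedly winding polylines traced through unstructured
#' data). Low f means a strong -- possibly nonlinear -- correlation; f is
#' invariant under rotation of the cloud.
#'
#' @param curve a [fit_pcop()] result.
#' @param points the n x 2 cloud the curve was fitted on.
#' @return f in \[0, 1\].
#' @export
uncorrelation_factor <- function(curve, points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  P <- curve$pops
  if (nrow(P) < 2) return(1)
  d2 <- .dist2_to_polyline(points, P)
  totvar <- mean((points[, 1] - mean(points[, 1]))^2 +
                 (points[, 2] - mean(points[, 2]))^2)
  if (totvar < 1e-300) return(1)
  clen <- sum(sqrt(rowSums(diff(P)^2)))
  # morphology mismatch: over-long or repeatedly winding polylines, and
  # curves whose extent does not span the cloud (e.g. a small loop threaded
  # through an unstructured blob)
  curve_diam <- .cloud_diameter(P)
  pen <- max(1, clen / (2 * curve$diameter), .total_winding(P) / 360,
             curve$diameter / max(curve_diam, 1e-12))
  min(1, max(0, mean(d2) / totvar * pen))
}

# squared distance of each point to the nearest polyline segment
.dist2_to_polyline <- function(points, P) {
  a <- P[-nrow(P), , drop = FALSE]
  b <- P[-1, , drop = FALSE]
  d2min <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(a))) {
    ab <- b[i, ] - a[i, ]
    L2 <- sum(ab^2)
    if (L2 == 0) {
      dx <- points[, 1] - a[i, 1]; dy <- points[, 2] - a[i, 2]
    } else {
      t <- ((points[, 1] - a[i, 1]) * ab[1] +
            (points[, 2] - a[i, 2]) * ab[2]) / L2
      t <- pmin(1, pmax(0, t))
      dx <- a[i, 1] + t * ab[1] - points[, 1]
      dy <- a[i, 2] + t * ab[2] - points[, 2]
    }
    d2min <- pmin(d2min, dx * dx + dy * dy)
  }
  d2min
}

#' Turn angles along a fitted curve
#'
#' For each POP, the interior angle (degrees; 180 = locally straight) between
#' the incoming and outgoing chords spanning `baseline_fraction` of the data
#' diameter of arc length on each side. Chord-based angles measure the change
#' in slope across a POP at a scale tied to the cloud, independent of how
#' finely the polyline is sampled. Open-curve POPs too close to an endpoint to
#' support at least half a baseline on both sides get `NA`; on closed curves
#' the chords wrap around.
#'
#' @param curve a [fit_pcop()] result.
#' @param baseline_fraction chord arc length per side as a fraction of the
#'   data diameter (default 0.3).
#' @return numeric vector of interior angles, one per POP, with attribute
#'   `"cross"` holding the z-component of the chord cross product (sign of
#'   the turn: positive = left/counter-clockwise).
#' @export
pop_turn_angles <- function(curve, baseline_fraction = 0.3) {
  P <- curve$pops
  n <- nrow(P)
  ang <- rep(NA_real_, n)
  crs <- rep(NA_real_, n)
  if (n >= 3) {
    s <- .arc_lengths(P)
    L <- s[n]
    b <- baseline_fraction * curve$diameter
    closed <- curve$closed
    for (i in seq_len(n)) {
      if (!closed && (i == 1 || i == n)) next
      jb <- .chord_index(s, L, i, -b, closed)
      jf <- .chord_index(s, L, i, +b, closed)
      if (is.na(jb) || is.na(jf)) next
      if (!closed) {
        if ((s[i] - s[jb]) < b / 2 || (s[jf] - s[i]) < b / 2) next
      }
      u <- P[i, ] - P[jb, ]
      v <- P[jf, ] - P[i, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) next
      dt <- max(-1, min(1, sum(u * v) / (nu * nv)))
      ang[i] <- 180 - acos(dt) * 180 / pi
      crs[i] <- u[1] * v[2] - u[2] * v[1]
    }
  }
  attr(ang, "cross") <- crs
  ang
}

# index of the POP at arc offset `off` (negative = backwards) from POP i
.chord_index <- function(s, L, i, off, closed) {
  n <- length(s)
  if (!closed) {
    target <- s[i] + off
    if (off < 0) {
      js <- which(s <= target)
      if (length(js)) max(js) else if (i > 1) 1L else NA_integer_
    } else {
      js <- which(s >= target)
      if (length(js)) min(js) else if (i < n) n else NA_integer_
    }
  } else {
    b <- abs(off)
    if (L <= 0) return(NA_integer_)
    j <- i
    for (k in seq_len(n - 1)) {
      j2 <- if (off < 0) ((i - 1 - k) %% n) + 1 else ((i - 1 + k) %% n) + 1
      d <- if (off < 0) (s[i] - s[j2]) %% L else (s[j2] - s[i]) %% L
      j <- j2
      if (d >= b) break
    }
    if (j == i) NA_integer_ else j
  }
}

#' Detect curvature points on a fitted curve
#'
#' A POP is flagged when its interior turn angle (see [pop_turn_angles()])
#' falls below `angle_threshold_deg`; maximal runs of consecutive flagged POPs
#' are merged into one curvature point at the sharpest POP of the run. On a
#' closed curve whose flagged run wraps the whole polyline (uniform curvature,
#' no distinguished corner) one curvature point is emitted per quarter turn of
#' accumulated winding.
#'
#' @param curve a [fit_pcop()] result.
#' @param angle_threshold_deg threshold in (0, 180\]; see
#'   [curvature_threshold()] for the gene-count-driven default.
#' @param baseline_fraction passed to [pop_turn_angles()].
#' @return data.frame with columns `pop_index`, `turn_angle_deg`,
#'   `turn_sign` (+1 left / -1 right); zero rows when the curve is straight.
#' @export
detect_curvature_points <- function(curve, angle_threshold_deg,
                                    baseline_fraction = 0.3) {
  if (!is.numeric(angle_threshold_deg) || length(angle_threshold_deg) != 1 ||
      angle_threshold_deg <= 0 || angle_threshold_deg > 180)
    stop("angle threshold must lie in (0, 180]", call. = FALSE)
  empty <- data.frame(pop_index = integer(0), turn_angle_deg = numeric(0),
                      turn_sign = numeric(0))
  P <- curve$pops
  if (nrow(P) < 3) return(empty)
  ang <- pop_turn_angles(curve, baseline_fraction)
  crs <- attr(ang, "cross")
  flagged <- !is.na(ang) & ang < angle_threshold_deg
  if (!any(flagged)) return(empty)

  n <- nrow(P)
  if (curve$closed && all(flagged[!is.na(ang)]) && sum(!is.na(ang)) >= n - 1) {
    # uniform curvature on a closed curve: one point per ~90 deg of winding
    k <- max(1L, as.integer(round(.total_winding(P) / 90)))
    s <- .arc_lengths(P)
    L <- s[n]
    targets <- (seq_len(k) - 1) * L / k
    idx <- vapply(targets, function(t) which.min(abs(s - t)), integer(1))
    idx <- sort(unique(idx))
    return(data.frame(pop_index = idx, turn_angle_deg = ang[idx],
                      turn_sign = sign(crs[idx])))
  }

  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  # wrap-merge first and last runs on closed curves
  idx_list <- lapply(runs, function(j) starts[j]:ends[j])
  if (curve$closed && length(idx_list) >= 2 &&
      idx_list[[1]][1] == 1 &&
      idx_list[[length(idx_list)]][length(idx_list[[length(idx_list)]])] == n) {
    idx_list[[1]] <- c(idx_list[[length(idx_list)]], idx_list[[1]])
    idx_list[[length(idx_list)]] <- NULL
  }
  picks <- vapply(idx_list, function(ix) ix[which.min(ang[ix])], integer(1))
  picks <- sort(unique(picks))
  data.frame(pop_index = picks, turn_angle_deg = ang[picks],
             turn_sign = sign(crs[picks]))
}

#' Export the POP polyline of a fitted curve as TSV
#'
#' @param curve a [fit_pcop()] result.
#' @param path output path.
#' @export
write_pcop <- function(curve, path) {
  df <- data.frame(pop = seq_len(nrow(curve$pops)),
                   x = curve$pops[, 1], y = curve$pops[, 2],
                   dir_x = curve$directions[, 1], dir_y = curve$directions[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
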