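#' Curve-type codes
#'
#' The shape taxonomy for pairwise expression relationships. Codes are stored
#' with the canonical orientation: the lexicographically smaller gene id on
#' the x axis.
#'
#' \describe{
#'   \item{LIN_POS / LIN_NEG}{straight, increasing / decreasing (coexpression)}
#'   \item{EXP_POS}{increasing, convex (y = e^x like)}
#'   \item{EXP_NEG}{decreasing, concave (y = -e^x like)}
#'   \item{LOG_POS}{increasing, concave (y = ln x like)}
#'   \item{LOG_NEG}{decreasing, convex (y = -ln x like)}
#'   \item{QUAD_POS / QUAD_NEG}{valley (y = x^2) / peak (y = -x^2)}
#'   \item{CUBIC_POS / CUBIC_NEG}{monotone with an inflection (y = +-x^3)}
#'   \item{SIDE_QUAD_POS / SIDE_QUAD_NEG}{sideways valley/peak (x = +-y^2)}
#'   \item{CLOSED}{closed curve (1 = x^2 + y^2 like)}
#'   \item{COMPLEX}{any other shape}
#' }
#' @export
CURVE_TYPES <- c("LIN_POS", "LIN_NEG", "EXP_POS", "EXP_NEG", "LOG_POS",
                 "LOG_NEG", "QUAD_POS", "QUAD_NEG", "CUBIC_POS", "CUBIC_NEG",
                 "SIDE_QUAD_POS", "SIDE_QUAD_NEG", "CLOSED", "COMPLEX")

#' Segment signature of a fitted curve
#'
#' Canonical shape intermediate between curvature detection and curve typing.
#' The curve is oriented so its net displacement along the dominant axis is
#' positive; it is then cut at the curvature points and each inter-curvature
#' segment is summarised by the signs of its net x and y displacement (a
#' 2-degree dead zone absorbs fit jitter). Turn direction signs come from the
#' chord cross product at each curvature point, weighted by how sharp the
#' turn is.
#'
#' @param curve a [fit_pcop()] result.
#' @param cps curvature points from [detect_curvature_points()].
#' @return A list of class `SegmentSignature`: `slope_signs`, `dx_signs`,
#'   `dy_signs` (one per segment, in -1/0/+1), `turn_direction_signs` and
#'   `turn_weights` (one per curvature point), `total_turning_deg`, `closed`.
#' @export
segment_signature <- function(curve, cps) {
  P <- curve$pops
  if (nrow(P) < 2) stop("curve has fewer than 2 POPs", call. = FALSE)
  if (curve$closed) {
    return(structure(list(slope_signs = integer(0), dx_signs = integer(0),
                          dy_signs = integer(0),
                          turn_direction_signs = integer(0),
                          turn_weights = numeric(0),
                          total_turning_deg = .total_winding(P),
                          closed = TRUE),
                     class = "SegmentSignature"))
  }
  idx <- cps$pop_index
  signs <- cps$turn_sign
  dev <- 180 - cps$turn_angle_deg
  # canonical traversal: increasing x, unless the net x displacement is
  # negligible (sideways shapes), then increasing y
  net <- P[nrow(P), ] - P[1, ]
  dead <- tan(2 * pi / 180)
  dom <- if (abs(net[1]) >= dead * abs(net[2])) 1L else 2L
  if (net[dom] < 0) {
    P <- P[nrow(P):1, , drop = FALSE]
    idx <- sort(nrow(P) + 1L - idx)
    signs <- -rev(signs)         # reversing traversal flips the turn sign
    dev <- rev(dev)
  }
  cuts <- c(1L, sort(idx), nrow(P))
  m <- length(cuts) - 1L
  dxs <- dys <- sls <- integer(m)
  for (j in seq_len(m)) {
    a <- P[cuts[j], ]; b <- P[cuts[j + 1L], ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    # dead zone: a component much smaller than the other counts as zero
    zx <- abs(dx) < dead * abs(dy)
    zy <- abs(dy) < dead * abs(dx)
    dxs[j] <- if (zx) 0L else as.integer(sign(dx))
    dys[j] <- if (zy) 0L else as.integer(sign(dy))
    sls[j] <- dxs[j] * dys[j]
  }
  structure(list(slope_signs = sls, dx_signs = dxs, dy_signs = dys,
                 turn_direction_signs = as.integer(signs),
                 turn_weights = dev,
                 total_turning_deg = .total_winding(P),
                 closed = FALSE),
            class = "SegmentSignature")
}

# compress consecutive equal non-zero signs, dropping zeros
.sign_pattern <- function(s) {
  s <- s[s != 0]
  if (!length(s)) return(integer(0))
  s[c(TRUE, diff(s) != 0)]
}

#' Classify a segment signature into a curve type
#'
#' Deterministic decision table over the signature: closed curves are
#' `CLOSED`; no curvature points gives `LIN_POS`/`LIN_NEG` by slope; curves
#' monotone in both axes split into exponential/logarithmic (one dominant
#' turn direction) or cubic (balanced opposing turn directions around an
#' inflection); curves monotone in x only are parabolic valleys/peaks, in y
#' only sideways parabolas; everything else is `COMPLEX`.
#'
#' @param sig a [segment_signature()].
#' @param n_curvature_points number of curvature points the signature was
#'   built from.
#' @param cubic_balance fraction of total turn weight the minority turn
#'   direction must reach before a monotone curve counts as cubic
#'   (default 0.35).
#' @return One code from [CURVE_TYPES].
#' @export
classify_signature <- function(sig, n_curvature_points = length(sig$turn_direction_signs),
                               cubic_balance = 0.35) {
  if (sig$closed) return("CLOSED")
  sls <- sig$slope_signs
  if (n_curvature_points == 0) {
    s <- .sign_pattern(sls)
    if (identical(s, 1L)) return("LIN_POS")
    if (identical(s, -1L)) return("LIN_NEG")
    return("COMPLEX")
  }
  dxp <- .sign_pattern(sig$dx_signs)
  dyp <- .sign_pattern(sig$dy_signs)
  mono_x <- length(dxp) == 1L
  mono_y <- length(dyp) == 1L
  if (mono_x && mono_y) {
    increasing <- dxp == dyp   # canonical orientation: dominant axis positive
    w <- sig$turn_weights
    s <- sig$turn_direction_signs
    wpos <- sum(w[s > 0]); wneg <- sum(w[s < 0])
    tot <- wpos + wneg
    if (tot > 0 && min(wpos, wneg) > cubic_balance * tot)
      return(if (increasing) "CUBIC_POS" else "CUBIC_NEG")
    convex <- wpos >= wneg   # net left turn
    if (increasing) return(if (convex) "EXP_POS" else "LOG_POS")
    return(if (convex) "LOG_NEG" else "EXP_NEG")
  }
  if (mono_x) {
    if (identical(dyp, c(-1L, 1L))) return("QUAD_POS")
    if (identical(dyp, c(1L, -1L))) return("QUAD_NEG")
    return("COMPLEX")
  }
  if (mono_y) {
    if (identical(dxp, c(-1L, 1L))) return("SIDE_QUAD_POS")
    if (identical(dxp, c(1L, -1L))) return("SIDE_QUAD_NEG")
    return("COMPLEX")
  }
  "COMPLEX"
}

#' Classify a fitted curve directly
#'
#' Convenience wrapper: detects curvature points at `angle_threshold_deg` and
#' classifies the resulting signature.
#'
#' @inheritParams detect_curvature_points
#' @return list with `curve_type`, `n_curvature_points`, `cps`.
#' @export
classify_curve <- function(curve, angle_threshold_deg, baseline_fraction = 0.3) {
  cps <- detect_curvature_points(curve, angle_threshold_deg, baseline_fraction)
  sig <- segment_signature(curve, cps)
  list(curve_type = classify_signature(sig, nrow(cps)),
       n_curvature_points = nrow(cps), cps = cps, signature = sig)
}

#' Transpose a curve type across the axis swap
#'
#' Maps the type of the (x, y) relationship to the type of the (y, x)
#' relationship (reflection across y = x). For increasing curves reflection
#' swaps convex and concave (EXP_POS <-> LOG_POS); for decreasing curves it
#' preserves them (the second derivative of the inverse of a decreasing f
#' has the sign of f''), so EXP_NEG and LOG_NEG are fixed points. Parabolas
#' swap with their sideways versions. The map is an involution.
#'
#' @param t a code from [CURVE_TYPES] (vectorised).
#' @return the transposed code(s).
#' @export
transpose_type <- function(t) {
  map <- c(LIN_POS = "LIN_POS", LIN_NEG = "LIN_NEG",
           EXP_POS = "LOG_POS", LOG_POS = "EXP_POS",
           EXP_NEG = "EXP_NEG", LOG_NEG = "LOG_NEG",
           QUAD_POS = "SIDE_QUAD_POS", SIDE_QUAD_POS = "QUAD_POS",
           QUAD_NEG = "SIDE_QUAD_NEG", SIDE_QUAD_NEG = "QUAD_NEG",
           CUBIC_POS = "CUBIC_POS", CUBIC_NEG = "CUBIC_NEG",
           CLOSED = "CLOSED", COMPLEX = "COMPLEX")
  bad <- !t %in% names(map)
  if (any(bad)) stop("unknown curve type: ", paste(t[bad], collapse = ", "),
                     call. = FALSE)
  unname(map[t])
}

#' Activation/deactivation semantics of a curve type
#'
#' Human-readable dependence between the two sets of coexpressed genes,
#' reading the curve with the first set on the x axis.
#'
#' @param t a code from [CURVE_TYPES] (vectorised).
#' @return character description(s).
#' @export
dependence_label <- function(t) {
  map <- c(
    LIN_POS = "positive coexpression (the two sets express together)",
    LIN_NEG = "inverse coexpression (one set rises as the other falls)",
    EXP_POS = "activation (first set must overexpress so the second starts to express)",
    EXP_NEG = "deactivation (overexpression of the first set deactivates the second)",
    LOG_POS = "saturating activation (second set switches on at low expression of the first, then saturates)",
    LOG_NEG = "mutual exclusion (one set must be deactivated so the other expresses)",
    QUAD_POS = "deactivation of second set at both over- and underexpression of first",
    QUAD_NEG = "activation of second set at both over- and underexpression of first",
    SIDE_QUAD_POS = "deactivation of first set at both over- and underexpression of second",
    SIDE_QUAD_NEG = "activation of first set at both over- and underexpression of second",
    CUBIC_POS = "graded activation with basal-level switching (inflected monotone dependence)",
    CUBIC_NEG = "graded deactivation with basal-level switching (inflected monotone dependence)",
    CLOSED = "cyclic dependence (the two sets alternate around a closed trajectory)",
    COMPLEX = "complex unclassified dependence"
  )
  bad <- !t %in% names(map)
  if (any(bad)) stop("unknown curve type: ", paste(t[bad], collapse = ", "),
                     call. = FALSE)
  unname(map[t])
}
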