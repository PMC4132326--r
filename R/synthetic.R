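# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Canonical curve-template transforms
#'
#' Template functions realising the curve taxonomy as generators. Each
#' template rescales the latent variable internally to its natural domain,
#' so the shape does not depend on the latent interval: `exp` acts on
#' \[0, 3\], `log` on \[0.1, 3\], `quad`/`cubic` on \[-1, 1\], and the
#' circle-arc pair `cos`/`sin` on \[0, 2*pi).
#'
#' @export
TRANSFORMS <- c("identity", "neg_identity", "exp", "neg_exp", "log",
                "neg_log", "quad", "neg_quad", "cubic", "neg_cubic",
                "cos", "sin")

.transform_fun <- function(name, interval) {
  a <- interval[1]; b <- interval[2]
  remap <- function(L, lo, hi) lo + (L - a) * (hi - lo) / (b - a)
  switch(name,
    identity     = function(L) L,
    neg_identity = function(L) -L,
    exp          = function(L) exp(remap(L, 0, 3)),
    neg_exp      = function(L) -exp(remap(L, 0, 3)),
    log          = function(L) log(remap(L, 0.1, 3)),
    neg_log      = function(L) -log(remap(L, 0.1, 3)),
    quad         = function(L) remap(L, -1, 1)^2,
    neg_quad     = function(L) -remap(L, -1, 1)^2,
    cubic        = function(L) remap(L, -1, 1)^3,
    neg_cubic    = function(L) -remap(L, -1, 1)^3,
    cos          = function(L) cos(remap(L, 0, 2 * pi * 59 / 60)),
    sin          = function(L) sin(remap(L, 0, 2 * pi * 59 / 60)),
    stop("unknown transform: ", name, call. = FALSE))
}

#' Generate the shared latent sample process
#'
#' A uniform grid over `interval` with seeded Gaussian jitter of standard
#' deviation one quarter of the grid spacing, clamped to the interval.
#' Deterministic per seed.
#'
#' @param n_samples number of samples (>= 20).
#' @param seed integer seed.
#' @param interval latent interval (default `c(0.1, 3.1)`).
#' @return numeric vector of length `n_samples`, with attributes
#'   `"interval"` and `"jitter_sd"`.
#' @export
gen_latent <- function(n_samples, seed, interval = c(0.1, 3.1)) {
  if (n_samples < 20) stop("n_samples must be at least 20", call. = FALSE)
  spacing <- diff(interval) / (n_samples - 1)
  jitter_sd <- spacing / 4
  L <- .with_seed(seed, {
    seq(interval[1], interval[2], length.out = n_samples) +
      stats::rnorm(n_samples, 0, jitter_sd)
  })
  L <- pmin(interval[2], pmax(interval[1], L))
  attr(L, "interval") <- interval
  attr(L, "jitter_sd") <- jitter_sd
  L
}

#' Generate one block of coexpressed genes
#'
#' Each gene is an affine rescaling of `transform(latent)` plus Gaussian
#' noise of standard deviation `noise_sd` (in standardized units), then
#' standardized, so genes within a block are mutually coexpressed by
#' construction.
#'
#' @param latent latent vector from [gen_latent()].
#' @param transform one of [TRANSFORMS].
#' @param n_genes number of genes in the block.
#' @param noise_sd noise standard deviation in standardized units.
#' @param seed integer seed.
#' @param prefix gene-id prefix (default `"G"`).
#' @return numeric matrix `n_genes` x `length(latent)` with rownames
#'   `<prefix>_G01`, ...
#' @export
gen_module <- function(latent, transform, n_genes, noise_sd, seed,
                       prefix = "G") {
  transform <- match.arg(transform, TRANSFORMS)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  interval <- attr(latent, "interval")
  if (is.null(interval)) interval <- range(latent)
  f <- .transform_fun(transform, interval)
  base <- f(as.numeric(latent))
  base <- (base - mean(base)) / stats::sd(base)
  n <- length(base)
  .with_seed(seed, {
    block <- matrix(NA_real_, n_genes, n)
    for (i in seq_len(n_genes)) {
      scale_i <- stats::runif(1, 0.5, 2)
      shift_i <- stats::runif(1, -1, 1)
      g <- shift_i + scale_i * (base + stats::rnorm(n, 0, noise_sd))
      block[i, ] <- (g - mean(g)) / stats::sd(g)
    }
    rownames(block) <- sprintf("%s_G%02d", prefix, seq_len(n_genes))
    block
  })
}

#' Curve type induced between two transforms (analytic)
#'
#' Ground-truth oracle for the generator: the curve type of the noiseless
#' parametric curve (f1(L), f2(L)) on a dense latent grid, derived from
#' monotonicity and the sign of the parametric curvature
#' dx * d2y - dy * d2x -- no curve fitting involved. The cos/sin pair is
#' `CLOSED` by construction.
#'
#' @param t1,t2 transforms from [TRANSFORMS]; `t1` is on the x axis.
#' @param interval latent interval.
#' @return a code from [CURVE_TYPES].
#' @export
induced_type <- function(t1, t2, interval = c(0.1, 3.1)) {
  t1 <- match.arg(t1, TRANSFORMS)
  t2 <- match.arg(t2, TRANSFORMS)
  if (t1 %in% c("cos", "sin") && t2 %in% c("cos", "sin") && t1 != t2)
    return("CLOSED")
  L <- seq(interval[1], interval[2], length.out = 4001)
  x <- .transform_fun(t1, interval)(L)
  y <- .transform_fun(t2, interval)(L)
  x <- (x - mean(x)) / stats::sd(x)
  y <- (y - mean(y)) / stats::sd(y)
  dx <- diff(x); dy <- diff(y)
  # orient: net x displacement positive (or net y when x is degenerate)
  dead <- tan(2 * pi / 180)
  netx <- x[length(x)] - x[1]; nety <- y[length(y)] - y[1]
  if ((abs(netx) >= dead * abs(nety) && netx < 0) ||
      (abs(netx) < dead * abs(nety) && nety < 0)) {
    x <- rev(x); y <- rev(y); dx <- diff(x); dy <- diff(y)
  }
  tol_x <- 1e-9 * max(abs(dx)); tol_y <- 1e-9 * max(abs(dy))
  sx <- .sign_pattern(as.integer(sign(dx)) * (abs(dx) > tol_x))
  sy <- .sign_pattern(as.integer(sign(dy)) * (abs(dy) > tol_y))
  mono_x <- length(sx) == 1L
  mono_y <- length(sy) == 1L
  # parametric curvature sign along the curve
  d2x <- diff(dx); d2y <- diff(dy)
  curv <- dx[-1] * d2y - dy[-1] * d2x
  scale_c <- max(abs(curv))
  if (mono_x && mono_y) {
    # straight when curvature is numerically nil relative to the extent
    chord_dev <- .max_chord_deviation(x, y)
    if (chord_dev < 1e-6) return(if (sy == 1L) "LIN_POS" else "LIN_NEG")
    sc <- .sign_pattern(as.integer(sign(curv)) * (abs(curv) > 1e-6 * scale_c))
    increasing <- sy == 1L
    if (length(sc) == 2L)
      return(if (increasing) "CUBIC_POS" else "CUBIC_NEG")
    convex <- identical(sc, 1L)
    if (increasing) return(if (convex) "EXP_POS" else "LOG_POS")
    return(if (convex) "LOG_NEG" else "EXP_NEG")
  }
  if (mono_x) {
    if (identical(sy, c(-1L, 1L))) return("QUAD_POS")
    if (identical(sy, c(1L, -1L))) return("QUAD_NEG")
    return("COMPLEX")
  }
  if (mono_y) {
    if (identical(sx, c(-1L, 1L))) return("SIDE_QUAD_POS")
    if (identical(sx, c(1L, -1L))) return("SIDE_QUAD_NEG")
    return("COMPLEX")
  }
  "COMPLEX"
}

.max_chord_deviation <- function(x, y) {
  n <- length(x)
  ux <- x[n] - x[1]; uy <- y[n] - y[1]
  L <- sqrt(ux^2 + uy^2)
  if (L == 0) return(Inf)
  max(abs((x - x[1]) * uy - (y - y[1]) * ux)) / L
}

#' Specification of a planted network dataset
#'
#' @param n_samples number of sample conditions.
#' @param modules list of module descriptions, each a list/vector with
#'   `id` (optional; default `M1`, `M2`, ...), `n_genes`, `noise_sd`,
#'   `transform` (one of [TRANSFORMS]).
#' @param intergroup optional named character map `"M1|M2" -> type` to
#'   validate the induced pairwise types against; unsatisfiable requests
#'   raise an error naming the offending pair.
#' @param background_genes number of pure-noise genes (default 0).
#' @param seed integer seed.
#' @param latent_interval latent interval (default `c(0.1, 3.1)`).
#' @return list of class `NetworkSpec`.
#' @export
network_spec <- function(n_samples, modules, intergroup = NULL,
                         background_genes = 0, seed = 1,
                         latent_interval = c(0.1, 3.1)) {
  if (length(modules) < 1) stop("need at least one module", call. = FALSE)
  if (length(modules) > 9) stop("at most 9 modules supported", call. = FALSE)
  modules <- lapply(seq_along(modules), function(i) {
    mod <- as.list(modules[[i]])
    if (is.null(mod$id)) mod$id <- sprintf("M%d", i)
    if (is.null(mod$noise_sd)) mod$noise_sd <- 0
    mod$n_genes <- as.integer(mod$n_genes)
    mod$noise_sd <- as.numeric(mod$noise_sd)
    mod$transform <- match.arg(mod$transform, TRANSFORMS)
    if (mod$n_genes < 1) stop("module n_genes must be >= 1", call. = FALSE)
    if (mod$noise_sd < 0) stop("module noise_sd must be >= 0", call. = FALSE)
    mod
  })
  ids <- vapply(modules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate module ids", call. = FALSE)
  structure(list(n_samples = n_samples, modules = modules,
                 intergroup = intergroup,
                 background_genes = as.integer(background_genes),
                 seed = as.integer(seed),
                 latent_interval = latent_interval),
            class = "NetworkSpec")
}

#' Generate an expression matrix with planted coexpressed modules
#'
#' All modules share one latent sample process; each module applies its
#' template transform, so every planted module pair exhibits the curve type
#' induced by the two transforms (computed analytically by
#' [induced_type()] and, when an `intergroup` map is requested, validated
#' against it). Background genes are independent standard Gaussian noise.
#' Deterministic per seed.
#'
#' @param spec a [network_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (`GroundTruth`: `membership` named gene -> module/`"background"`,
#'   `intergroup` named map `"Mi|Mj" -> type` with the lexicographically
#'   smaller module on x, `signature` in [network_signature()] format).
#' @export
gen_network_dataset <- function(spec) {
  stopifnot(inherits(spec, "NetworkSpec"))
  latent <- gen_latent(spec$n_samples, spec$seed, spec$latent_interval)
  ids <- vapply(spec$modules, `[[`, character(1), "id")
  # induced pairwise types, validated against the requested map
  induced <- character(0)
  if (length(ids) >= 2) {
    pr <- utils::combn(seq_along(ids), 2)
    for (p in seq_len(ncol(pr))) {
      i <- pr[1, p]; j <- pr[2, p]
      # canonical orientation: lexicographically smaller module id on x
      if (ids[i] > ids[j]) { tmp <- i; i <- j; j <- tmp }
      key <- paste(ids[i], ids[j], sep = "|")
      induced[key] <- induced_type(spec$modules[[i]]$transform,
                                   spec$modules[[j]]$transform,
                                   spec$latent_interval)
      if (!is.null(spec$intergroup) && key %in% names(spec$intergroup) &&
          spec$intergroup[[key]] != induced[key])
        stop(sprintf(
          "unsatisfiable intergroup request for %s: transforms induce %s, not %s",
          key, induced[key], spec$intergroup[[key]]), call. = FALSE)
    }
    if (!is.null(spec$intergroup)) {
      extra <- setdiff(names(spec$intergroup), names(induced))
      if (length(extra))
        stop("intergroup map names unknown module pair(s): ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  blocks <- lapply(seq_along(spec$modules), function(i) {
    mod <- spec$modules[[i]]
    gen_module(latent, mod$transform, mod$n_genes, mod$noise_sd,
               seed = spec$seed + i, prefix = mod$id)
  })
  vals <- do.call(rbind, blocks)
  membership <- stats::setNames(
    rep(ids, vapply(spec$modules, `[[`, integer(1), "n_genes")),
    rownames(vals))
  if (spec$background_genes > 0) {
    bg <- .with_seed(spec$seed + 1000L, {
      b <- matrix(stats::rnorm(spec$background_genes * spec$n_samples),
                  spec$background_genes, spec$n_samples)
      rownames(b) <- sprintf("BG_%03d", seq_len(spec$background_genes))
      b
    })
    vals <- rbind(vals, bg)
    membership <- c(membership,
                    stats::setNames(rep("background", nrow(bg)), rownames(bg)))
  }
  colnames(vals) <- sprintf("S%03d", seq_len(spec$n_samples))
  m <- expression_matrix(vals)
  signature <- paste0(length(ids), ":",
                      paste(sort(unname(induced), method = "radix"),
                            collapse = ","))
  truth <- structure(list(membership = membership, intergroup = induced,
                          signature = signature),
                     class = "GroundTruth")
  list(matrix = m, truth = truth)
}
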