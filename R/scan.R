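#' Correlation (uncorrelation-factor) acceptance threshold
#'
#' Gene-count-driven threshold on the uncorrelation factor f: a pair is
#' accepted (correlated enough) when its f does not exceed the threshold.
#' The threshold loosens for small matrices, so that enough relationships
#' survive to assemble skeleton networks, and collapses for very large ones:
#'
#' \deqn{0.12 \times \frac{1600}{n} - \left(\frac{n}{40000}\right)^{18}}
#'
#' @param num_genes number of analysable genes (>= 2).
#' @return the threshold value.
#' @export
f_threshold <- function(num_genes) {
  if (!is.numeric(num_genes) || length(num_genes) != 1 || num_genes < 2)
    stop("num_genes must be a single number >= 2", call. = FALSE)
  val <- 0.12 * (1600 / num_genes) - (num_genes / 40000)^18
  if (val <= 0)
    stop(sprintf(paste0("degenerate f threshold (%.4g) at %d genes; ",
                        "set an explicit f_threshold_override"),
                 val, as.integer(num_genes)), call. = FALSE)
  val
}

#' Curvature (linearity) threshold in degrees
#'
#' Gene-count-driven turn-angle threshold separating linear from nonlinear
#' relationships: a POP whose interior turn angle falls below the threshold
#' is a curvature point. The threshold is higher (more readily flagging
#' curvature, i.e. more restrictive for calling pairs linear) in matrices
#' with fewer genes:
#'
#' \deqn{160 - \frac{15.0/20000 + 14.0/18400}{2} \times n}
#'
#' @param num_genes number of analysable genes (>= 2).
#' @return threshold in degrees, in (0, 180).
#' @export
curvature_threshold <- function(num_genes) {
  if (!is.numeric(num_genes) || length(num_genes) != 1 || num_genes < 2)
    stop("num_genes must be a single number >= 2", call. = FALSE)
  val <- 160 - ((15.0 / 20000 + 14.0 / 18400) / 2) * num_genes
  if (val <= 0)
    stop(sprintf(paste0("degenerate curvature threshold (%.4g) at %d genes; ",
                        "set an explicit curvature_threshold_override"),
                 val, as.integer(num_genes)), call. = FALSE)
  val
}

#' Scan configuration
#'
#' @param f_threshold_override optional fixed f threshold in (0, 1]
#'   (replaces the [f_threshold()] formula and disables online correction
#'   of it).
#' @param curvature_threshold_override optional fixed curvature threshold in
#'   (0, 180].
#' @param online_correction logical; adjust the f threshold from the
#'   projected number of passing pairs (default TRUE).
#' @param target_pass_band length-2 numeric (min, max) target count of
#'   accepted pairs; default `c(2, 20) * num_genes`, resolved at scan time.
#' @param min_complete_samples minimum complete-case samples for a pair
#'   (default 20); pairs below it are skipped.
#' @param bandwidth_fraction,step_fraction,min_neighbourhood PCOP fit
#'   parameters, see [fit_pcop()].
#' @param baseline_fraction chord baseline for turn angles, see
#'   [pop_turn_angles()].
#' @return list of class `ScanConfig`.
#' @export
scan_config <- function(f_threshold_override = NULL,
                        curvature_threshold_override = NULL,
                        online_correction = TRUE,
                        target_pass_band = NULL,
                        min_complete_samples = 20,
                        bandwidth_fraction = 0.2,
                        step_fraction = 0.05,
                        min_neighbourhood = 10,
                        baseline_fraction = 0.3) {
  if (!is.null(f_threshold_override) &&
      (f_threshold_override <= 0 || f_threshold_override > 1))
    stop("f_threshold_override must lie in (0, 1]", call. = FALSE)
  if (!is.null(curvature_threshold_override) &&
      (curvature_threshold_override <= 0 || curvature_threshold_override > 180))
    stop("curvature_threshold_override must lie in (0, 180]", call. = FALSE)
  if (!is.null(target_pass_band) &&
      (length(target_pass_band) != 2 || target_pass_band[1] > target_pass_band[2]))
    stop("target_pass_band must be (min, max) with min <= max", call. = FALSE)
  structure(list(f_threshold_override = f_threshold_override,
                 curvature_threshold_override = curvature_threshold_override,
                 online_correction = isTRUE(online_correction),
                 target_pass_band = target_pass_band,
                 min_complete_samples = min_complete_samples,
                 bandwidth_fraction = bandwidth_fraction,
                 step_fraction = step_fraction,
                 min_neighbourhood = min_neighbourhood,
                 baseline_fraction = baseline_fraction),
            class = "ScanConfig")
}

# thresholds actually in force for a matrix under a config
.resolve_thresholds <- function(num_genes, config) {
  fthr <- if (!is.null(config$f_threshold_override))
    config$f_threshold_override else f_threshold(num_genes)
  cthr <- if (!is.null(config$curvature_threshold_override))
    config$curvature_threshold_override else curvature_threshold(num_genes)
  band <- if (!is.null(config$target_pass_band))
    config$target_pass_band else c(2, 20) * num_genes
  list(f = fthr, curvature = cthr, band = band)
}

#' Fit and classify one gene pair
#'
#' Standardizes the complete-case samples of the pair (the lexicographically
#' smaller gene on x), fits the PCOP, and classifies: rejected when f exceeds
#' `f_thr`; otherwise linear when no curvature point is found at
#' `curvature_thr`, else nonlinear with its curve type.
#'
#' @param m a standardized [expression_matrix()].
#' @param gene_a,gene_b gene ids (stored sorted).
#' @param config a [scan_config()].
#' @param f_thr,curvature_thr thresholds in force (default: resolved from
#'   the matrix size and config).
#' @return one-row data.frame: `gene_a`, `gene_b`, `f`,
#'   `n_curvature_points`, `curve_type`, `relation_class`
#'   (`"linear"|"nonlinear"|"rejected"`), `n_samples`; or `NULL` when the
#'   pair has fewer complete samples than `config$min_complete_samples`
#'   (skip, reported via attribute `"skip_reason"` on NULL is not possible,
#'   so skips are logged by [scan_all()]).
#' @export
scan_pair <- function(m, gene_a, gene_b, config = scan_config(),
                      f_thr = NULL, curvature_thr = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!gene_a %in% m$gene_ids) stop("unknown gene: ", gene_a, call. = FALSE)
  if (!gene_b %in% m$gene_ids) stop("unknown gene: ", gene_b, call. = FALSE)
  if (is.null(f_thr) || is.null(curvature_thr)) {
    thr <- .resolve_thresholds(length(m$gene_ids), config)
    if (is.null(f_thr)) f_thr <- min(1, thr$f)
    if (is.null(curvature_thr)) curvature_thr <- thr$curvature
  }
  g <- sort(c(gene_a, gene_b), method = "radix")
  x <- m$values[g[1], ]
  y <- m$values[g[2], ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < config$min_complete_samples) return(NULL)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  pts <- cbind((x - mean(x)) / stats::sd(x), (y - mean(y)) / stats::sd(y))
  curve <- fit_pcop(pts, config$bandwidth_fraction, config$step_fraction,
                    config$min_neighbourhood)
  cls <- classify_curve(curve, curvature_thr, config$baseline_fraction)
  # f at the clip ceiling means no detectable correlation at all; such a
  # pair is never "highly correlated", whatever the formula threshold says
  relation <- if (curve$f > f_thr || curve$f >= 1) "rejected"
              else if (cls$n_curvature_points == 0 && !curve$closed) "linear"
              else "nonlinear"
  ctype <- if (relation == "linear") {
    if (cls$curve_type %in% c("LIN_POS", "LIN_NEG")) cls$curve_type else "COMPLEX"
  } else cls$curve_type
  data.frame(gene_a = g[1], gene_b = g[2], f = curve$f,
             n_curvature_points = cls$n_curvature_points,
             curve_type = ctype, relation_class = relation,
             n_samples = sum(ok), stringsAsFactors = FALSE)
}

#' One online-correction step for the f threshold
#'
#' From the pairs already analysed the projected final number of accepted
#' pairs is `n_passed / n_pairs_done * n_pairs_total`; above the target band
#' the threshold is tightened by 5 percent, below it loosened by 5 percent but
#' never beyond `ceiling` (the formula value), inside it left unchanged.
#'
#' @param state list with `n_pairs_total`, `n_pairs_done`, `n_passed`,
#'   `current_f_threshold`.
#' @param band numeric (min, max) target count of accepted pairs.
#' @param ceiling_f upper bound for loosening.
#' @return the new f threshold.
#' @export
update_threshold_online <- function(state, band, ceiling_f) {
  stopifnot(state$n_pairs_done > 0)
  projected <- state$n_passed / state$n_pairs_done * state$n_pairs_total
  thr <- state$current_f_threshold
  if (projected > band[2]) thr * 0.95
  else if (projected < band[1]) min(thr * 1.05, ceiling_f)
  else thr
}

#' Scan all gene pairs of an expression matrix
#'
#' Standardizes the matrix (dropping constant genes), fits a PCOP to every
#' unordered gene pair in lexicographic order, and classifies each pair as
#' linear, nonlinear (with curve type) or rejected. With
#' `online_correction` the f threshold is recalibrated every 1 percent of
#' the pair sequence from the projected number of accepted pairs; the final
#' corrected threshold is applied uniformly to all pairs, so the output is
#' independent of pair order. Pairs with too few complete samples are
#' skipped and logged.
#'
#' @param m an [expression_matrix()] (raw or standardized).
#' @param config a [scan_config()].
#' @return list of class `ScanResult`: `table` (one row per analysed pair,
#'   including rejected ones), `state` (final `ScanState`), `thresholds`
#'   (f and curvature thresholds in force), `skipped` (data.frame of skipped
#'   pairs with reasons), `num_genes`.
#' @export
scan_all <- function(m, config = scan_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mz <- standardize(m)
  genes <- sort(mz$gene_ids, method = "radix")
  n <- length(genes)
  if (n < 2) stop("need at least 2 analysable genes", call. = FALSE)
  thr <- .resolve_thresholds(n, config)
  cthr <- thr$curvature
  f_start <- min(1, thr$f)

  pairs <- utils::combn(genes, 2)
  n_total <- ncol(pairs)
  rows <- vector("list", n_total)
  skipped <- list()
  for (i in seq_len(n_total)) {
    rec <- scan_pair(mz, pairs[1, i], pairs[2, i], config,
                     f_thr = Inf, curvature_thr = cthr)
    if (is.null(rec)) {
      skipped[[length(skipped) + 1]] <- data.frame(
        gene_a = pairs[1, i], gene_b = pairs[2, i],
        reason = sprintf("fewer than %d complete samples",
                         config$min_complete_samples),
        stringsAsFactors = FALSE)
      rows[[i]] <- NULL
    } else {
      rows[[i]] <- rec
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  # online threshold correction over the lexicographic sequence
  f_final <- f_start
  if (config$online_correction && is.null(config$f_threshold_override) &&
      !is.null(tab) && nrow(tab) > 0) {
    cadence <- max(1L, as.integer(ceiling(nrow(tab) / 100)))
    state <- list(n_pairs_total = nrow(tab), n_pairs_done = 0L, n_passed = 0L,
                  current_f_threshold = f_start)
    for (i in seq_len(nrow(tab))) {
      state$n_pairs_done <- i
      if (tab$f[i] <= state$current_f_threshold)
        state$n_passed <- state$n_passed + 1L
      if (i %% cadence == 0L)
        state$current_f_threshold <-
          update_threshold_online(state, thr$band, f_start)
    }
    f_final <- state$current_f_threshold
  }

  if (!is.null(tab) && nrow(tab) > 0) {
    rejected <- tab$f > f_final | tab$f >= 1
    tab$relation_class[rejected] <- "rejected"
    # accepted pairs keep their curvature-based split
    acc <- !rejected
    tab$relation_class[acc & tab$n_curvature_points == 0 &
                       tab$curve_type != "CLOSED"] <- "linear"
    tab$relation_class[acc & (tab$n_curvature_points > 0 |
                              tab$curve_type == "CLOSED")] <- "nonlinear"
    rownames(tab) <- NULL
  }
  n_passed <- if (is.null(tab)) 0L else sum(tab$relation_class != "rejected")
  state <- list(n_pairs_total = n_total,
                n_pairs_done = if (is.null(tab)) 0L else nrow(tab),
                n_passed = n_passed, current_f_threshold = f_final)
  structure(list(table = tab, state = state,
                 thresholds = list(f_initial = f_start, f_final = f_final,
                                   curvature = cthr),
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else data.frame(gene_a = character(0),
                                           gene_b = character(0),
                                           reason = character(0)),
                 num_genes = n),
            class = "ScanResult")
}

#' @export
print.ScanResult <- function(x, ...) {
  tb <- table(factor(x$table$relation_class,
                     levels = c("linear", "nonlinear", "rejected")))
  cat(sprintf(paste0("ScanResult: %d genes, %d pairs ",
                     "(%d linear, %d nonlinear, %d rejected), f threshold %.4g\n"),
              x$num_genes, x$state$n_pairs_done,
              tb["linear"], tb["nonlinear"], tb["rejected"],
              x$state$current_f_threshold))
  invisible(x)
}

#' Write a relationship table as TSV
#'
#' @param scan a `ScanResult` (or its `table`).
#' @param path output path.
#' @export
write_relationships <- function(scan, path) {
  tab <- if (inherits(scan, "ScanResult")) scan$table else scan
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relationship table written by [write_relationships()]
#'
#' @param path TSV path.
#' @return data.frame with the scan table columns.
#' @export
read_relationships <- function(path) {
  if (!file.exists(path)) stop("relationships file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene_a", "gene_b", "f", "n_curvature_points", "curve_type",
            "relation_class")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("malformed relationships file; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}
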