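#' ROI deltaF/F time course with fixed time bins
#'
#' Computes the relative fluorescence change of a region of interest in
#' time bins (0.5 s by default): per bin, the mean ROI fluorescence divided
#' by the pre-stimulus ROI baseline mean, minus one. Frames are assigned to
#' bins by their acquisition time, so non-integer frames-per-bin values are
#' handled without drift; with `bin_s = 1/rate` the trace has one bin per
#' frame.
#'
#' @param stack an [image_stack()].
#' @param roi logical matrix selecting ROI pixels; defaults to the whole
#'   exposed field.
#' @param bin_s bin width in seconds (at least one frame).
#' @param baseline_s pre-stimulus baseline duration in seconds.
#' @return A data frame with `time` (bin start, s) and `dff`.
#' @export
timecourse <- function(stack, roi = NULL, bin_s = 0.5, baseline_s = 2) {
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  rate <- stack$frame_rate_hz
  if (bin_s < 1 / rate) stopf("`bin_s` must be at least one frame period")
  d <- dim(stack$frames)
  if (is.null(roi)) roi <- matrix(TRUE, d[1L], d[2L])
  if (!identical(dim(roi), d[1:2])) stopf("ROI shape does not match frames")
  if (!any(roi)) stopf("ROI is empty")
  roi_trace <- vapply(seq_len(d[3L]),
                      function(i) mean(stack$frames[, , i][roi]),
                      numeric(1))
  onset <- stack$stimulus_onset_frame
  b0 <- onset - as.integer(floor(baseline_s * rate))
  if (b0 < 1L || onset - 1L < b0)
    stopf("baseline window is empty or outside the stack")
  base <- mean(roi_trace[b0:(onset - 1L)])
  if (base <= 0) stopf("non-positive ROI baseline")
  tvec <- (seq_len(d[3L]) - 1) / rate
  bin <- floor(round(tvec / bin_s, 9))   # guard against float jitter
  dff <- tapply(roi_trace, bin, mean) / base - 1
  data.frame(time = sort(unique(bin)) * bin_s, dff = as.numeric(dff),
             row.names = NULL)
}

#' Stimulus-response curve from trial sets
#'
#' For each value of a stimulation parameter (pulse count or current), the
#' response peak is the maximum of the post-onset binned ROI deltaF/F
#' trace, computed per trial and averaged; the standard error across trials
#' is reported.
#'
#' @param trials_by_param named list: parameter value (name, coercible to
#'   numeric) to list of trial [image_stack()]s.
#' @param roi,bin_s,baseline_s passed to [timecourse()].
#' @return A data frame with `param`, `n_trials`, `peak_mean`, `peak_se`,
#'   sorted by `param`.
#' @export
stimulus_response_curve <- function(trials_by_param, roi = NULL,
                                    bin_s = 0.5, baseline_s = 2) {
  if (!is.list(trials_by_param) || length(trials_by_param) < 2L)
    stopf("at least 2 parameter values are required")
  params <- suppressWarnings(as.numeric(names(trials_by_param)))
  if (anyNA(params)) stopf("list names must be numeric parameter values")
  rows <- lapply(seq_along(params), function(i) {
    trials <- trials_by_param[[i]]
    peaks <- vapply(trials, function(st) {
      tc <- timecourse(st, roi = roi, bin_s = bin_s, baseline_s = baseline_s)
      onset_t <- (st$stimulus_onset_frame - 1) / st$frame_rate_hz
      max(tc$dff[tc$time + bin_s > onset_t])
    }, numeric(1))
    data.frame(param = params[i], n_trials = length(peaks),
               peak_mean = mean(peaks),
               peak_se = sd(peaks) / sqrt(length(peaks)))
  })
  out <- do.call(rbind, rows)
  out[order(out$param), , drop = FALSE]
}

#' Quadrant partition of the imaged field into piriform subregions
#'
#' Splits the field into the four subregions APCd, APCv, PPCd and PPCv
#' (dorsal and ventral parts of the anterior and posterior piriform
#' cortex) by one anteroposterior column split and one dorsoventral row
#' split. Columns up to `ap_split_col` are anterior and rows up to
#' `dv_split_row` are dorsal (anterior left, dorsal up). The anatomical
#' boundaries are inputs, not derived from the images.
#'
#' @param dim integer `c(height, width)` of the map.
#' @param ap_split_col last anterior column (0 .. width; 0 makes the
#'   anterior subregions empty).
#' @param dv_split_row last dorsal row (0 .. height).
#' @return A `subregion_partition`: a character label matrix with levels
#'   `APCd`, `APCv`, `PPCd`, `PPCv` and attribute `subregions`.
#' @export
partition_subregions <- function(dim, ap_split_col = floor(dim[2L] / 2),
                                 dv_split_row = floor(dim[1L] / 2)) {
  h <- dim[1L]; w <- dim[2L]
  if (ap_split_col < 0 || ap_split_col > w)
    stopf("`ap_split_col` outside the image (0..%d)", w)
  if (dv_split_row < 0 || dv_split_row > h)
    stopf("`dv_split_row` outside the image (0..%d)", h)
  anterior <- matrix(rep(seq_len(w) <= ap_split_col, each = h), h, w)
  dorsal <- matrix(rep(seq_len(h) <= dv_split_row, times = w), h, w)
  labels <- matrix("", h, w)
  labels[anterior & dorsal] <- "APCd"
  labels[anterior & !dorsal] <- "APCv"
  labels[!anterior & dorsal] <- "PPCd"
  labels[!anterior & !dorsal] <- "PPCv"
  structure(labels, class = c("subregion_partition", "matrix"),
            subregions = c("APCd", "APCv", "PPCd", "PPCv"),
            ap_split_col = ap_split_col, dv_split_row = dv_split_row)
}

#' Subregion response vector
#'
#' Summarizes a response map per subregion as (i) the mean deltaF/F over
#' the subregion and (ii) the fraction of subregion pixels in the
#' significance mask (the positive responsive mask by default, i.e. the
#' "significantly responsive areas"; the full two-sided mask as an
#' option). The 8-element vector (4 means followed by 4 fractions) is the
#' feature vector used for response-pattern clustering.
#'
#' @param map a [pixel_ttest()] response map.
#' @param partition a [partition_subregions()] of the same shape.
#' @param mask `"responsive"` (default) or `"significant"`.
#' @param label optional condition/replicate label attached to the vector.
#' @return A named numeric vector of length 8 (class `response_vector`)
#'   with attributes `label` and `empty_subregions` (labels of empty
#'   subregions, whose fractions are `NA`).
#' @export
response_vector <- function(map, partition, mask = c("responsive",
                                                     "significant"),
                            label = NULL) {
  mask <- match.arg(mask)
  if (!inherits(map, "response_map")) stopf("`map` must be a response_map")
  if (!identical(dim(unclass(partition)), dim(map$mean_dff)))
    stopf("partition shape does not match the map")
  sel <- if (mask == "responsive") map$responsive_mask else map$sig_mask
  regions <- attr(partition, "subregions")
  labels <- unclass(partition)
  means <- fracs <- setNames(numeric(length(regions)), regions)
  empty <- character(0)
  for (r in regions) {
    px <- labels == r
    if (!any(px)) {
      means[r] <- NA_real_; fracs[r] <- NA_real_
      empty <- c(empty, r)
    } else {
      means[r] <- mean(map$mean_dff[px])
      fracs[r] <- sum(sel & px) / sum(px)
    }
  }
  if (length(empty))
    warning("empty subregion(s): ", paste(empty, collapse = ", "),
            "; fractions set to NA", call. = FALSE)
  structure(c(setNames(means, paste0("mean.", regions)),
              setNames(fracs, paste0("frac.", regions))),
            class = "response_vector", label = label,
            empty_subregions = empty)
}

#' Euclidean distance matrix between response vectors
#'
#' @param vectors list (length >= 2) of equal-length numeric vectors,
#'   typically [response_vector()]s; names or vector labels become
#'   dimnames.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(vectors) {
  if (!is.list(vectors) || length(vectors) < 2L)
    stopf("at least 2 vectors are required")
  len <- length(vectors[[1L]])
  for (v in vectors)
    if (length(v) != len) stopf("vectors differ in length")
  X <- do.call(rbind, lapply(vectors, as.numeric))
  labs <- names(vectors)
  if (is.null(labs))
    labs <- vapply(seq_along(vectors), function(i) {
      l <- attr(vectors[[i]], "label")
      if (is.null(l)) sprintf("v%d", i) else as.character(l)
    }, character(1))
  rownames(X) <- make.unique(labs)
  as.matrix(dist(X))
}

#' Agglomerative clustering of response patterns
#'
#' Hierarchical clustering (average linkage / UPGMA by default) of a
#' distance matrix; merge heights are reported as linkage distances. When
#' class labels (for example stimulus conditions) are supplied, the
#' within-class and between-class pairwise distances are summarized as
#' mean +/- SD and compared with a two-sample two-tailed t-test
#' (pooled-variance Student test, with a permutation test available).
#'
#' @param distmat symmetric distance matrix with zero diagonal (e.g. from
#'   [pairwise_distances()]).
#' @param classes optional vector of class labels, one per row.
#' @param method linkage passed to [stats::hclust()]: `"average"`
#'   (default), `"single"` or `"complete"`.
#' @param permutations if positive, adds a permutation p-value for the
#'   within/between comparison based on this many label shuffles.
#' @return A `cluster_result`: the `hclust` tree, `linkage_distances`
#'   (merge heights), `labels`, the distance matrix, and (with classes)
#'   `within_between`, a list with the within/between means, SDs, counts,
#'   t statistic and p-value(s).
#' @export
hierarchical_cluster <- function(distmat, classes = NULL,
                                 method = c("average", "single",
                                            "complete"),
                                 permutations = 0) {
  method <- match.arg(method)
  distmat <- as.matrix(distmat)
  n <- nrow(distmat)
  if (n < 2L) stopf("at least 2 observations are required")
  if (!isTRUE(all.equal(distmat, t(distmat))) ||
      any(abs(diag(distmat)) > 1e-12))
    stopf("`distmat` must be symmetric with zero diagonal")
  hc <- hclust(as.dist(distmat), method = method)
  res <- list(tree = hc, linkage_distances = hc$height,
              labels = hc$labels, distmat = distmat, method = method)
  if (!is.null(classes)) {
    if (length(classes) != n) stopf("`classes` must have one label per row")
    pair <- which(upper.tri(distmat), arr.ind = TRUE)
    d <- distmat[pair]
    same <- classes[pair[, 1L]] == classes[pair[, 2L]]
    if (!any(same) || all(same))
      stopf("need both within- and between-class pairs")
    wt <- d[same]; bt <- d[!same]
    tt <- t.test(wt, bt, var.equal = TRUE)
    wb <- list(within_mean = mean(wt), within_sd = sd(wt),
               n_within = length(wt),
               between_mean = mean(bt), between_sd = sd(bt),
               n_between = length(bt),
               t = unname(tt$statistic), p_value = tt$p.value)
    if (permutations > 0) {
      obs <- mean(bt) - mean(wt)
      perm <- vapply(seq_len(permutations), function(i) {
        cl <- sample(classes)
        s <- cl[pair[, 1L]] == cl[pair[, 2L]]
        if (!any(s) || all(s)) return(NA_real_)
        mean(d[!s]) - mean(d[s])
      }, numeric(1))
      wb$p_permutation <- (1 + sum(perm >= obs, na.rm = TRUE)) /
        (1 + sum(!is.na(perm)))
    }
    res$within_between <- wb
    res$classes <- classes
    res$top_split <- cutree(hc, k = 2L)
  }
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d leaves, %s linkage\n",
              length(x$labels), x$method))
  cat("  linkage distances:",
      paste(signif(x$linkage_distances, 4), collapse = ", "), "\n")
  if (!is.null(x$within_between)) {
    wb <- x$within_between
    cat(sprintf("  within %.3g +/- %.3g (n=%d), between %.3g +/- %.3g (n=%d), p = %.3g\n",
                wb$within_mean, wb$within_sd, wb$n_within, wb$between_mean,
                wb$between_sd, wb$n_between, wb$p_value))
  }
  invisible(x)
}

# constructs used in the transgenic line summary
TBX_CONSTRUCTS <- c("Tbx5.0gV", "Tbx2.6gV", "Tbx1.0gV", "MCE-gV", "Tbx-spH")

#' Transgenic line expression summary
#'
#' `read_expression_table()` loads a line-summary table of transgene
#' expression outcomes: one row per transgenic founder/line, with the
#' construct name and logical flags per expression site. The packaged
#' table (`inst/extdata/tbx21_line_summary.csv`) transcribes the published
#' aggregate counts for the Tbx21 constructs (Tbx5.0gV 15/17 mitral/tufted;
#' Tbx2.6gV 2/43 mitral/tufted and 27/43 olfactory pathway; Tbx1.0gV 0/3;
#' MCE-gV 4/10; Tbx-spH 1/5); line identifiers named in the original
#' report are used where available and placeholders otherwise, so
#' row-level flags beyond the printed aggregates are reconstructions.
#'
#' `expression_rate()` tabulates one (construct, site) cell:
#' the positive count, the total number of founders/lines carrying the
#' construct, and the percentage rounded to the nearest integer.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return `read_expression_table()`: a data frame with `construct`,
#'   `line_id` and logical site columns.
#' @export
read_expression_table <- function(path = system.file(
  "extdata", "tbx21_line_summary.csv", package = "sphmap")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct", "line_id")
  if (!all(need %in% names(tab)))
    stopf("expression table must have columns: %s (missing: %s)",
          paste(need, collapse = ", "),
          paste(setdiff(need, names(tab)), collapse = ", "))
  bad <- setdiff(unique(tab$construct), TBX_CONSTRUCTS)
  if (length(bad))
    stopf("unknown construct(s): %s", paste(bad, collapse = ", "))
  for (col in setdiff(names(tab), need)) tab[[col]] <- as.logical(tab[[col]])
  tab
}

#' @param table a data frame from [read_expression_table()].
#' @param construct construct name, one of
#'   `Tbx5.0gV`, `Tbx2.6gV`, `Tbx1.0gV`, `MCE-gV`, `Tbx-spH`.
#' @param site expression-site column name, for example `"mitral_tufted"`
#'   or `"olfactory_pathway"`.
#' @rdname read_expression_table
#' @return `expression_rate()`: a list with `positive`, `total`, `percent`.
#' @export
expression_rate <- function(table, construct, site) {
  if (!construct %in% table$construct)
    stopf("construct '%s' not present in the table", construct)
  if (!site %in% names(table))
    stopf("unknown expression site '%s'", site)
  sub <- table[table$construct == construct, site]
  if (length(sub) == 0L) stopf("empty construct subset")
  positive <- sum(sub, na.rm = TRUE)
  total <- length(sub)
  list(positive = positive, total = total,
       percent = round(100 * positive / total))
}
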