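#' Response map for one condition
#'
#' Runs the per-condition analysis chain: every trial (stimulus and blank)
#' is photobleaching-corrected against the mean of the blank trials, a
#' windowed differential image is formed, band-pass filtered, and the two
#' groups of filtered images are compared by the pixel-wise t-test. The
#' shared blank-mean subtraction cancels exactly in both the difference of
#' group means and the within-group variances, so the test retains its
#' nominal level.
#'
#' @param stim_stacks,blank_stacks lists of [image_stack()]s (>= 2 each).
#' @param windows an [analysis_windows()].
#' @param filter a [filter_params()]; `NULL` skips filtering.
#' @param alpha significance level.
#' @param ... passed to [pixel_ttest()].
#' @return A [pixel_ttest()] response map.
#' @export
map_condition <- function(stim_stacks, blank_stacks,
                          windows = analysis_windows(),
                          filter = filter_params(), alpha = 0.01, ...) {
  one <- function(st) {
    d <- differential_image(bleach_correct(st, blank_stacks), windows)
    if (!is.null(filter)) d <- bandpass_filter(d, filter)
    d
  }
  stim_dffs <- lapply(stim_stacks, one)
  blank_dffs <- lapply(blank_stacks, one)
  pixel_ttest(stim_dffs, blank_dffs, alpha = alpha, ...)
}

#' End-to-end mapping, quantification and clustering pipeline
#'
#' Orchestrates the full imaging analysis over a set of trial stacks that
#' may span several conditions and replicates: per (replicate, condition),
#' trials are bleach-corrected against that replicate's blank trials,
#' converted to windowed differential images, band-pass filtered, averaged
#' and tested pixel-wise against the blanks; each map is then summarized
#' as a subregion response vector, and with two or more maps the vectors
#' are clustered hierarchically with condition labels as classes.
#'
#' When `out_dir` is given, the run writes: per-map mean deltaF/F TIFFs
#' and PNG overlays, the response vectors and pairwise distances as CSV,
#' the dendrogram as JSON, and a metadata JSON capturing every analysis
#' parameter actually used (windows in frames, cutoffs, alpha, splits), so
#' a run is reproducible from its output alone.
#'
#' @param stacks list of [image_stack()]s; blank trials are identified by
#'   their stimulus kind and must be present in every replicate.
#' @param windows an [analysis_windows()].
#' @param filter a [filter_params()].
#' @param alpha pixel-test significance level.
#' @param ap_split_col,dv_split_row subregion boundaries (defaults: field
#'   centre).
#' @param mask mask used for subregion fractions and overlays
#'   (`"responsive"` or `"significant"`).
#' @param linkage clustering linkage.
#' @param out_dir optional output directory.
#' @return A list with `maps` (named `replicate.condition`), `vectors`,
#'   `distances`, `clustering` (or `NULL` with fewer than 2 maps or a
#'   single condition) and `params`.
#' @export
run_mapping_pipeline <- function(stacks, windows = analysis_windows(),
                                 filter = filter_params(), alpha = 0.01,
                                 ap_split_col = NULL, dv_split_row = NULL,
                                 mask = "responsive",
                                 linkage = "average", out_dir = NULL) {
  if (!is.list(stacks) || !length(stacks))
    stopf("`stacks` must be a non-empty list of image_stack objects")
  reps <- vapply(stacks, `[[`, integer(1), "replicate")
  maps <- list()
  vectors <- list()
  classes <- character(0)
  shape <- dim(stacks[[1L]]$frames)[1:2]
  part <- partition_subregions(
    shape,
    ap_split_col = if (is.null(ap_split_col)) floor(shape[2L] / 2)
    else ap_split_col,
    dv_split_row = if (is.null(dv_split_row)) floor(shape[1L] / 2)
    else dv_split_row)
  for (r in sort(unique(reps))) {
    rs <- stacks[reps == r]
    blank <- Filter(function(s) is_blank(s$stimulus), rs)
    stim <- Filter(function(s) !is_blank(s$stimulus), rs)
    conds <- unique(vapply(stim, function(s) s$stimulus$label, character(1)))
    if (!length(blank))
      stopf("replicate %d has no blank trials (conditions: %s)",
            r, paste(conds, collapse = ", "))
    for (cond in conds) {
      cs <- Filter(function(s) s$stimulus$label == cond, stim)
      key <- sprintf("rep%d.%s", r, cond)
      maps[[key]] <- map_condition(cs, blank, windows = windows,
                                   filter = filter, alpha = alpha)
      vectors[[key]] <- response_vector(maps[[key]], part, mask = mask,
                                        label = key)
      classes <- c(classes, cond)
    }
  }
  distances <- NULL
  clustering <- NULL
  if (length(vectors) >= 2L) {
    distances <- pairwise_distances(vectors)
    # class comparison needs at least one within- and one between-class pair
    use_classes <- length(unique(classes)) >= 2L && anyDuplicated(classes)
    clustering <- if (use_classes)
      hierarchical_cluster(distances, classes = classes, method = linkage)
    else hierarchical_cluster(distances, method = linkage)
  }
  params <- list(windows = unclass(windows),
                 stim_window_frames_rel = {
                   rate <- stacks[[1L]]$frame_rate_hz
                   c(floor(windows$stim_start_s * rate),
                     ceiling(windows$stim_end_s * rate) - 1)
                 },
                 filter = if (is.null(filter)) NULL else unclass(filter),
                 alpha = alpha,
                 mask = mask,
                 ap_split_col = attr(part, "ap_split_col"),
                 dv_split_row = attr(part, "dv_split_row"),
                 linkage = linkage,
                 n_stacks = length(stacks))
  res <- list(maps = maps, vectors = vectors, distances = distances,
              clustering = clustering, partition = part, params = params)
  if (!is.null(out_dir)) write_mapping_outputs(res, stacks, out_dir)
  res
}

write_mapping_outputs <- function(res, stacks, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- vapply(stacks, `[[`, integer(1), "replicate")
  for (key in names(res$maps)) {
    map <- res$maps[[key]]
    rng <- range(map$mean_dff)
    norm <- if (diff(rng) > 0) (map$mean_dff - rng[1L]) / diff(rng)
    else map$mean_dff * 0
    tiff::writeTIFF(norm, file.path(out_dir, paste0(key, "_mean_dff.tif")),
                    bits.per.sample = 32L)
    r <- as.integer(sub("^rep(\\d+)\\..*$", "\\1", key))
    rs <- stacks[reps == r]
    blank <- Filter(function(s) is_blank(s$stimulus), rs)
    anatomy <- rowMeans(blank[[1L]]$frames, dims = 2L)
    png::writePNG(make_overlay(map, anatomy, mask = res$params$mask),
                  file.path(out_dir, paste0(key, "_overlay.png")))
  }
  vec_tab <- do.call(rbind, lapply(names(res$vectors), function(k)
    cbind(data.frame(map = k), as.data.frame(t(as.numeric(res$vectors[[k]])),
      col.names = names(res$vectors[[k]])))))
  names(vec_tab)[-1L] <- names(res$vectors[[1L]])
  write.csv(vec_tab, file.path(out_dir, "response_vectors.csv"),
            row.names = FALSE)
  if (!is.null(res$distances))
    write.csv(res$distances, file.path(out_dir, "distances.csv"))
  if (!is.null(res$clustering)) {
    hc <- res$clustering$tree
    jsonlite::write_json(
      list(merge = hc$merge, height = hc$height, labels = hc$labels,
           method = res$clustering$method,
           within_between = res$clustering$within_between),
      file.path(out_dir, "dendrogram.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$params, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Conservation and motif-scan pipeline
#'
#' Computes the sliding-window identity profile of an aligned pair, calls
#' conserved elements at the VISTA-style parameters, scans the ungapped
#' reference for the consensus T-box motif, and (with `out_dir`) writes
#' the profile TSV, the elements as BED, the hits as TSV and a metadata
#' JSON.
#'
#' @param pair an [alignment_pair()] or path to an aligned FASTA file.
#' @param window_bp,identity_threshold,min_width_bp conservation
#'   parameters.
#' @param motif,max_mismatch,both_strands motif-scan parameters.
#' @param out_dir optional output directory.
#' @return A list with `profile`, `elements`, `hits` and `params`.
#' @export
run_conservation_pipeline <- function(pair, window_bp = 100,
                                      identity_threshold = 80,
                                      min_width_bp = 100,
                                      motif = "TCACACCT", max_mismatch = 1,
                                      both_strands = TRUE, out_dir = NULL) {
  if (is.character(pair)) pair <- read_alignment_fasta(pair)
  if (!inherits(pair, "alignment_pair"))
    stopf("`pair` must be an alignment_pair or FASTA path")
  profile <- sliding_identity(pair, window_bp = window_bp)
  elements <- call_conserved(profile,
                             identity_threshold = identity_threshold,
                             min_width_bp = min_width_bp)
  ref_ungapped <- gsub("-", "", pair$reference, fixed = TRUE)
  hits <- motif_scan(ref_ungapped, motif = motif,
                     max_mismatch = max_mismatch,
                     both_strands = both_strands)
  params <- list(window_bp = window_bp,
                 identity_threshold = identity_threshold,
                 min_width_bp = min_width_bp, motif = motif,
                 max_mismatch = max_mismatch, both_strands = both_strands,
                 reference = pair$name, ref_start = pair$ref_start)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_tsv(profile, file.path(out_dir, "conservation.tsv"))
    write_elements_bed(elements, file.path(out_dir, "conserved.bed"),
                       chrom = if (nzchar(pair$name)) pair$name else "ref",
                       ref_start = pair$ref_start)
    write_hits_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
    jsonlite::write_json(params, file.path(out_dir, "scan_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profile = profile, elements = elements, hits = hits, params = params)
}

#' Expression-rate report across constructs and sites
#'
#' Tabulates [expression_rate()] for every construct and expression-site
#' column of a line-summary table.
#'
#' @param table a data frame from [read_expression_table()], or a CSV
#'   path.
#' @return A data frame with one row per (construct, site):
#'   `construct`, `site`, `positive`, `total`, `percent`.
#' @export
report_expression_rates <- function(table = read_expression_table()) {
  if (is.character(table)) table <- read_expression_table(table)
  if (!nrow(table)) stopf("expression table is empty")
  sites <- setdiff(names(table), c("construct", "line_id"))
  rows <- list()
  for (construct in unique(table$construct)) {
    for (site in sites) {
      r <- expression_rate(table, construct, site)
      rows[[length(rows) + 1L]] <-
        data.frame(construct = construct, site = site,
                   positive = r$positive, total = r$total,
                   percent = r$percent)
    }
  }
  do.call(rbind, rows)
}
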