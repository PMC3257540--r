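# independent brute-force oracles and small fixtures used across tests

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# reverse complement by character table, independent of Biostrings
revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# per-window identity by explicit per-window counting
oracle_window_identity <- function(ref, partner, w) {
  r <- strsplit(toupper(ref), "")[[1]]
  p <- strsplit(toupper(partner), "")[[1]]
  keep <- r != "-"
  r <- r[keep]; p <- p[keep]
  L <- length(r)
  acgt <- c("A", "C", "G", "T")
  vapply(seq_len(L - w + 1), function(s) {
    n_match <- 0
    for (j in s:(s + w - 1))
      if (r[j] %in% acgt && p[j] %in% acgt && r[j] == p[j])
        n_match <- n_match + 1
    100 * n_match / w
  }, numeric(1))
}

# exhaustive motif enumeration over positions and strands
oracle_motif_hits <- function(seq, motif, max_mismatch, both = TRUE) {
  s <- strsplit(toupper(seq), "")[[1]]
  pats <- list("+" = toupper(motif))
  if (both) pats[["-"]] <- revcomp_chr(motif)
  out <- list()
  for (strand in names(pats)) {
    pc <- strsplit(pats[[strand]], "")[[1]]
    m <- length(pc)
    if (m > length(s)) next
    for (pos in seq_len(length(s) - m + 1)) {
      mm <- sum(s[pos:(pos + m - 1)] != pc)
      if (mm <= max_mismatch)
        out[[length(out) + 1]] <- data.frame(position = pos,
                                             strand = strand,
                                             mismatches = mm)
    }
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$position, tab$strand), ]
  rownames(tab) <- NULL
  tab
}

# reduced-field configuration used by the heavier simulation tests
small_config <- function(...) {
  synthetic_config(height_px = 64, width_px = 84, ...)
}

# quiet, fast configuration for deterministic arithmetic checks
clean_config <- function(...) {
  defaults <- list(height_px = 16, width_px = 20, shot_noise_sd = 0,
                   global_fluct_amplitude = 0, bleach_tau_s = Inf)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# image stack from an explicit frame array with the default timing
make_stack <- function(frames, onset = 11L, rate = 5, mm_per_px = 0.02,
                       stimulus = blank_stimulus(), trial_id = "t") {
  image_stack(frames, rate, mm_per_px, onset, stimulus, trial_id)
}

const_frames <- function(h, w, nf, value = 100) array(value, c(h, w, nf))

# minimal response_map for quantification tests
fake_map <- function(mean_dff, sig) {
  structure(list(mean_dff = mean_dff, diff_dff = mean_dff,
                 t_stat = mean_dff * 0, p_value = 1 - sig,
                 sig_mask = sig, responsive_mask = sig,
                 alpha = 0.01, n_stim_trials = 10, n_blank_trials = 10,
                 var_equal = TRUE, p_adjust = "none"),
            class = "response_map")
}
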