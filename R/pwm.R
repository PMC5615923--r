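# Integer log-odds score matrix for a motif: round(log2(pwm/bg) / bin).
# Discretizing both the DP and the scanner onto the same integer grid makes
# the score p-value exact with respect to the discretized score.
pwm_int_scores <- function(motif, bin = 1e-3) {
  lo <- log2(motif$pwm / motif$background)
  round(lo / bin)
}

# Exact distribution of the integer score of a background-generated
# width-mer, by dynamic programming (convolution column by column).
# Returns list(scores = integer grid, tail = P(S >= score)).
pwm_score_distribution <- function(motif, bin = 1e-3) {
  si <- pwm_int_scores(motif, bin)
  bg <- motif$background
  # support grows column by column; cur[k] = P(partial score == cur_min + k - 1)
  cur <- 1
  cur_min <- 0
  for (j in seq_len(ncol(si))) {
    new_min <- cur_min + min(si[, j])
    new_max <- cur_min + length(cur) - 1 + max(si[, j])
    new <- numeric(new_max - new_min + 1)
    for (b in seq_len(4)) {
      sh <- cur_min + si[b, j] - new_min
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new
    cur_min <- new_min
  }
  scores <- seq(cur_min, cur_min + length(cur) - 1)
  tail_p <- rev(cumsum(rev(cur)))
  list(scores = scores, prob = cur, tail = tail_p)
}

# P(background width-mer integer score >= s) for integer scores s.
pwm_tail_p <- function(dist, s) {
  p <- numeric(length(s))
  below <- s <= dist$scores[1]
  above <- s > dist$scores[length(dist$scores)]
  inside <- !below & !above
  p[below] <- 1
  p[above] <- 0
  if (any(inside)) {
    idx <- s[inside] - dist$scores[1] + 1
    p[inside] <- dist$tail[idx]
  }
  p
}

reverse_complement_motif <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pwm <- motif$pwm[comp[rownames(motif$pwm)], rev(seq_len(motif$width)), drop = FALSE]
  rownames(pwm) <- names(comp)
  bg <- motif$background[comp[names(motif$background)]]
  names(bg) <- names(comp)
  structure(list(pwm = pwm, background = bg, width = motif$width,
                 consensus = motif$consensus),
            class = "motif_model")
}

scan_one_strand <- function(codes, si) {
  w <- ncol(si)
  L <- length(codes)
  if (L < w) return(integer(0))
  n_pos <- L - w + 1
  # row 5 of the lookup handles N: log-ratio 0
  lut <- rbind(si, 0L)
  total <- integer(n_pos)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_pos - 1)]
    cj[cj == 0L] <- 5L
    total <- total + lut[cbind(cj, j)]
  }
  total
}

#' Scan a sequence for motif hits with exact score p-values
#'
#' Slides the motif over both strands, scoring each window by the summed
#' log2(pwm/background) odds, and reports windows whose score p-value — the
#' probability that a background-generated width-mer scores at least as high,
#' computed exactly by dynamic programming over the discretized score
#' distribution — is at or below `p_threshold`. `N` positions contribute a
#' log-odds of 0.
#'
#' @param sequence a single DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param motif a `motif_model` (see [foxo_motif()]).
#' @param p_threshold score p-value cut-off (default 1e-4, the conventional
#'   promoter-scanning threshold).
#' @param bin log-odds discretization bin (default 1e-3).
#' @param dist optional precomputed score distribution (recycled across
#'   sequences by [scan_promoters()]).
#' @return A tibble of hits: `position` (1-based start on the forward
#'   strand), `strand`, `score` (log2 odds), `p`. Sequences shorter than the
#'   motif return an empty table.
#' @export
scan_pwm <- function(sequence, motif, p_threshold = 1e-4, bin = 1e-3,
                     dist = NULL) {
  stopifnot(inherits(motif, "motif_model"), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  if (is.null(dist)) dist <- pwm_score_distribution(motif, bin)
  ok <- dist$tail <= p_threshold
  t_min <- if (any(ok)) dist$scores[which(ok)[1]] else Inf
  out <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") motif else reverse_complement_motif(motif)
    si <- pwm_int_scores(m, bin)
    total <- scan_one_strand(codes, si)
    hit <- which(total >= t_min)
    if (length(hit)) {
      out[[strand]] <- tibble(
        position = hit,
        strand = strand,
        score = total[hit] * bin,
        p = pwm_tail_p(dist, total[hit])
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(position = integer(), strand = character(),
                  score = numeric(), p = numeric()))
  }
  dplyr::arrange(res, .data$position, .data$strand)
}

#' Scan a promoter set and report genes with motif hits
#'
#' @param sequences named character vector of promoter sequences (the window
#'   is expected to be the 1,000 bp upstream of each TSS).
#' @inheritParams scan_pwm
#' @return A tibble: `gene`, `n_hits`, `has_hit`, `best_p`.
#' @export
scan_promoters <- function(sequences, motif, p_threshold = 1e-4, bin = 1e-3) {
  dist <- pwm_score_distribution(motif, bin)
  hits <- purrr::map(sequences, scan_pwm, motif = motif,
                     p_threshold = p_threshold, bin = bin, dist = dist)
  tibble(
    gene = names(sequences),
    n_hits = vapply(hits, nrow, integer(1)),
    best_p = vapply(hits, function(h) if (nrow(h)) min(h$p) else NA_real_,
                    numeric(1))
  ) |>
    dplyr::mutate(has_hit = .data$n_hits > 0)
}

#' Write motif hits as a BED-like TSV (0-based, half-open)
#'
#' @param hits tibble from [scan_pwm()].
#' @param gene sequence/gene name for the first column.
#' @param motif the scanned `motif_model` (for the hit width).
#' @param path output path.
#' @export
write_motif_hits_bed <- function(hits, gene, motif, path) {
  bed <- tibble(
    chrom = gene,
    start = hits$position - 1L,
    end = hits$position - 1L + motif$width,
    name = motif$consensus,
    score = hits$score,
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
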