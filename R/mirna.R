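# Simplified miRNA binding-site scanner: seed-plus-extension Watson-Crick
# complementarity with G:U wobble, applied to mRNA-sense windows around
# editing sites before and after the edit. This deliberately replaces a full
# thermodynamic predictor; its evidence is the pairing identity at the
# edited base.

#' Read miRNA sequences from FASTA
#'
#' @param path FASTA of mature miRNA sequences (5'->3', RNA or DNA
#'   alphabet; U is normalised to T internally).
#' @return tibble `id`, `seq` (DNA alphabet).
#' @export
read_mirna_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  mirna_set(sub("\\s.*$", "", names(s)), as.character(s))
}

#' Construct a validated miRNA set
#'
#' @param id miRNA identifiers.
#' @param seq 5'->3' sequences (U allowed).
#' @return tibble `id`, `seq` with U normalised to T.
#' @export
mirna_set <- function(id, seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  if (any(nchar(seq) < 18L)) abort("miRNA sequences must be >= 18 nt")
  if (any(grepl("[^ACGT]", seq))) abort("miRNA alphabet must be A/C/G/U(T)")
  tibble(id = id, seq = seq)
}

#' Build reference and edited mRNA-sense windows around editing sites
#'
#' Both windows are the mRNA-sense sequence (reverse-complemented for
#' minus-strand genes) of total length `width` centred on the site — by
#' default 25 bases upstream and 24 downstream of the centre — and differ
#' at exactly the centre base. Windows clipped at a contig edge are flagged
#' `truncated`.
#'
#' @param sites tibble with `chrom`, `pos`, `ref`, `alt` and either
#'   `strand` or a `gene_id` resolvable through `models`.
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param models gene-model tibble for strand lookup when needed.
#' @param width total window length (default 50).
#' @return `sites` plus `strand`, `ref_window`, `edited_window`, `center`
#'   (1-based index of the edited base in the window) and `truncated`.
#' @export
build_windows <- function(sites, genome, models = NULL, width = 50L) {
  strand <- sites[["strand"]]
  if (is.null(strand)) {
    if (is.null(models)) abort("need sites$strand or gene models")
    spans <- transcript_spans(models)
    strand <- vapply(seq_len(nrow(sites)), function(i) {
      hit <- spans[spans$chrom == sites$chrom[i] &
                     spans$start <= sites$pos[i] &
                     spans$end >= sites$pos[i], ]
      if (nrow(hit)) hit$strand[1] else "+"
    }, character(1))
  }
  up <- width %/% 2L
  down <- width - up - 1L
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- sites
  out$strand <- strand
  out$ref_window <- out$edited_window <- character(nrow(sites))
  out$center <- integer(nrow(sites))
  out$truncated <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    len <- lens[[sites$chrom[i]]]
    if (strand[i] == "+") {
      lo <- p - up; hi <- p + down
    } else {
      lo <- p - down; hi <- p + up
    }
    clip_lo <- max(1L, lo); clip_hi <- min(len, hi)
    out$truncated[i] <- clip_lo != lo || clip_hi != hi
    s <- genome_slice(genome, sites$chrom[i], clip_lo, clip_hi)
    center <- p - clip_lo + 1L
    alt <- sites$alt[i]
    if (strand[i] == "-") {
      s <- revcomp(s)
      center <- nchar(s) - center + 1L
      alt <- complement_base(alt)
    }
    edited <- s
    substr(edited, center, center) <- alt
    out$ref_window[i] <- s
    out$edited_window[i] <- edited
    out$center[i] <- center
  }
  out
}

# pair classification: miRNA base (5'->3') against target base, antiparallel
pair_class <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "C" & t == "G") | (m == "G" & t == "C")
  wobble <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, 2L, ifelse(wobble, 1L, 0L))
}

#' Scan a window for miRNA binding sites
#'
#' A hit requires at least `seed_min` consecutive Watson-Crick pairs
#' between miRNA seed positions 2-8 and the window (miRNA and target
#' antiparallel). Each seed anchor is extended gap-free in both directions
#' while bases keep pairing (Watson-Crick or G:U wobble), and scored +2 per
#' Watson-Crick pair and +1 per wobble.
#'
#' @param window target sequence, mRNA sense (DNA alphabet).
#' @param mirna_seq one miRNA sequence, 5'->3' (U allowed).
#' @param seed_min minimum consecutive seed pairs (default 7, i.e. the full
#'   2-8 seed).
#' @param score_min minimum total score to report (default 0).
#' @return tibble of hits: `t_start`, `t_end` (window positions paired),
#'   `m_start`, `m_end` (miRNA positions), `score`.
#' @export
scan_mirna <- function(window, mirna_seq, seed_min = 7L, score_min = 0L) {
  mirna_seq <- chartr("Uu", "Tt", toupper(mirna_seq))
  window <- toupper(window)
  wlen <- nchar(window)
  mlen <- nchar(mirna_seq)
  empty <- tibble(t_start = integer(), t_end = integer(),
                  m_start = integer(), m_end = integer(), score = integer())
  if (wlen < seed_min) return(empty)
  wb <- strsplit(window, "", fixed = TRUE)[[1]]
  mb <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  seed_hi <- min(8L, mlen)
  if (seed_hi - seed_min + 1L < 2L) return(empty)
  # candidate alignments: revcomp of each seed_min-long run inside seed 2..8
  aligns <- integer(0)
  for (i in 2:(seed_hi - seed_min + 1L)) {
    j <- i + seed_min - 1L
    pat <- revcomp(substr(mirna_seq, i, j))
    m <- gregexpr(pat, window, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    # target s..s+(j-i) pairs miRNA j..i  =>  alignment constant a = s + j
    aligns <- c(aligns, as.integer(m) + j)
  }
  aligns <- unique(aligns)
  hits <- list()
  for (a in aligns) {
    m_range <- seq_len(mlen)
    t_for_m <- a - m_range
    valid <- t_for_m >= 1L & t_for_m <= wlen
    sc <- rep(0L, mlen)
    sc[valid] <- pair_class(mb[m_range[valid]], wb[t_for_m[valid]])
    # the maximal gap-free paired run that contains a >= seed_min WC seed run
    paired <- sc > 0L
    runs <- rle(paired)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      m_lo <- starts[k]; m_hi <- ends[k]
      seg <- m_lo:m_hi
      wc_in_seed <- sc[seg] == 2L & seg >= 2L & seg <= seed_hi
      r <- rle(wc_in_seed)
      if (!any(r$values & r$lengths >= seed_min)) next
      hits[[length(hits) + 1L]] <- tibble(
        t_start = a - m_hi, t_end = a - m_lo,
        m_start = m_lo, m_end = m_hi,
        score = sum(sc[seg])
      )
    }
  }
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits) |>
    dplyr::distinct() |>
    dplyr::filter(.data$score >= score_min) |>
    dplyr::arrange(.data$t_start)
}

#' Report miRNA binding sites gained or lost by editing
#'
#' Scans the reference and edited windows of every site against every
#' miRNA; a site/miRNA pair is classified by the presence of a hit whose
#' paired target range covers the edited base: `gained` (edited only),
#' `lost` (reference only), `retained` (both) or `absent` (neither). The
#' base pair formed at the edited position is recorded miRNA-base |
#' target-base in the RNA alphabet (e.g. `"C|G"`).
#'
#' @param sites tibble with `chrom`, `pos`, `ref`, `alt` (+ `strand` or
#'   resolvable via `models`).
#' @param mirnas tibble from [mirna_set()]/[read_mirna_fasta()].
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param models gene-model tibble (strand lookup).
#' @param width,seed_min passed to [build_windows()]/[scan_mirna()].
#' @return tibble: site keys, `mirna_id`, `status`, `score_before`,
#'   `score_after`, `pairing_at_edit`.
#' @export
rebind_report <- function(sites, mirnas, genome, models = NULL, width = 50L,
                          seed_min = 7L) {
  win <- build_windows(sites, genome, models, width = width)
  rows <- list()
  for (i in seq_len(nrow(win))) {
    for (k in seq_len(nrow(mirnas))) {
      center <- win$center[i]
      score_pair <- function(window) {
        h <- scan_mirna(window, mirnas$seq[k], seed_min = seed_min)
        h <- h[h$t_start <= center & h$t_end >= center, ]
        if (!nrow(h)) return(list(score = 0L, pair = NA_character_))
        best <- h[which.max(h$score), ]
        # miRNA position paired with the centre: a = t + m is constant
        m_at <- (best$t_end + best$m_start) - center
        mb <- substr(mirnas$seq[k], m_at, m_at)
        tb <- substr(window, center, center)
        list(score = best$score,
             pair = paste0(chartr("T", "U", mb), "|", chartr("T", "U", tb)))
      }
      before <- score_pair(win$ref_window[i])
      after <- score_pair(win$edited_window[i])
      status <- if (before$score > 0 && after$score > 0) "retained"
        else if (before$score > 0) "lost"
        else if (after$score > 0) "gained"
        else "absent"
      rows[[length(rows) + 1L]] <- tibble(
        chrom = win$chrom[i], pos = win$pos[i], ref = win$ref[i],
        alt = win$alt[i], mirna_id = mirnas$id[k], status = status,
        score_before = before$score, score_after = after$score,
        pairing_at_edit = if (status %in% c("gained", "retained"))
          after$pair else before$pair
      )
    }
  }
  dplyr::bind_rows(rows)
}
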