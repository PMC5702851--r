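# Site discovery: read preprocessing, duplicate marking, pileup base
# counting, candidate detection, the filtration cascade, and cluster-based
# editing calling.

#' Trim and quality-filter raw reads
#'
#' Removes the first `trim_n` bases from the 5' end of each read and drops
#' reads whose mean Phred quality after trimming falls below `qual_cutoff`.
#' Reads shorter than or equal to `trim_n` are dropped and counted in the
#' `dropped_short` attribute.
#'
#' @param reads FASTQ tibble (`id`, `seq`, `qual`), Phred+33.
#' @param trim_n bases trimmed from the 5' end (default 10).
#' @param qual_cutoff minimum mean quality to keep a read (default 30).
#' @return filtered FASTQ tibble; attributes `dropped_short` and
#'   `dropped_quality` count removals.
#' @export
trim_and_filter_reads <- function(reads, trim_n = 10L, qual_cutoff = 30) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  long_enough <- nchar(reads$seq) > trim_n
  n_short <- sum(!long_enough)
  if (n_short > 0) {
    warn(sprintf("%d read(s) shorter than trim length dropped", n_short))
  }
  out <- reads[long_enough, ]
  if (trim_n > 0L) {
    out$seq <- stringr::str_sub(out$seq, trim_n + 1L)
    out$qual <- stringr::str_sub(out$qual, trim_n + 1L)
  }
  mean_q <- vapply(qual_to_int(out$qual), mean, numeric(1))
  keep <- mean_q >= qual_cutoff
  res <- out[keep, ]
  attr(res, "dropped_short") <- n_short
  attr(res, "dropped_quality") <- sum(!keep)
  res
}

#' Mark PCR duplicates among aligned reads
#'
#' Reads sharing (chromosome, position, mate position) within a sample are
#' considered PCR duplicates of one fragment; all but one are flagged. The
#' survivor is the read with the highest base-quality sum (ties broken by
#' read name), so the outcome does not depend on input order among equals.
#'
#' @param reads aligned-read tibble (see [read_sam()]), sorted by
#'   (chrom, pos) within each sample.
#' @return the same tibble with the `duplicate` flag set.
#' @export
mark_duplicates <- function(reads) {
  chk <- reads |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos), .groups = "drop")
  if (!all(chk$sorted)) abort("reads must be sorted by (chrom, pos)")
  qsum <- vapply(qual_to_int(reads$qual), sum, numeric(1))
  reads |>
    dplyr::mutate(.qsum = qsum) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$pos, .data$mate_pos) |>
    dplyr::mutate(duplicate = {
      ord <- order(-.data$.qsum, .data$qname)
      dup <- rep(TRUE, dplyr::n())
      dup[ord[1]] <- FALSE
      dup
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".qsum")
}

#' Pileup base counts from aligned reads
#'
#' Counts, at every covered reference position, the bases carried by
#' non-duplicate reads with mapping quality at least `min_mapq`. `N` bases
#' are excluded from counts; positions with zero surviving coverage emit no
#' column. Alignments are assumed match-only (read `i`-th base sits at
#' `pos + i - 1`).
#'
#' @param reads aligned-read tibble (duplicate-marked).
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_baseq optional minimum base quality (default 0 = unused).
#' @return tibble with `chrom`, `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`,
#'   `mean_mapq`.
#' @export
pileup <- function(reads, genome, min_mapq = 20L, min_baseq = 0L) {
  r <- reads[!reads$duplicate & reads$mapq >= min_mapq, ]
  if (!nrow(r)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  depth = integer(), A = integer(), C = integer(),
                  G = integer(), T = integer(), mean_mapq = numeric()))
  }
  widths <- nchar(r$seq)
  ends <- r$pos + widths - 1L
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  too_far <- ends > lens[r$chrom] | r$pos < 1L
  if (any(too_far)) abort("read extends beyond chromosome end")
  base <- unlist(strsplit(r$seq, "", fixed = TRUE), use.names = FALSE)
  long <- tibble(
    chrom = rep(r$chrom, widths),
    pos = unlist(lapply(seq_len(nrow(r)), function(i)
      seq.int(r$pos[i], ends[i])), use.names = FALSE),
    base = base,
    mapq = rep(r$mapq, widths)
  )
  if (min_baseq > 0L) {
    bq <- unlist(qual_to_int(r$qual), use.names = FALSE)
    long <- long[bq >= min_baseq, ]
  }
  long <- long[long$base %in% BASES, ]
  cols <- long |>
    dplyr::count(.data$chrom, .data$pos, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in setdiff(BASES, names(cols))) cols[[b]] <- 0L
  mq <- long |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(mean_mapq = mean(.data$mapq), .groups = "drop")
  cols |>
    dplyr::left_join(mq, by = c("chrom", "pos")) |>
    dplyr::mutate(
      depth = .data$A + .data$C + .data$G + .data$T,
      ref = genome_base(genome, .data$chrom, .data$pos)
    ) |>
    dplyr::filter(.data$ref %in% BASES) |>
    dplyr::select("chrom", "pos", "ref", "depth", "A", "C", "G", "T",
                  "mean_mapq") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

alt_counts <- function(columns) {
  cnt <- as.matrix(columns[, BASES])
  ref_idx <- match(columns$ref, BASES)
  cnt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  # highest non-reference count; ties broken by fixed base order A<C<G<T
  alt_idx <- max.col(cnt, ties.method = "first")
  tibble(alt = BASES[alt_idx],
         alt_count = cnt[cbind(seq_len(nrow(cnt)), alt_idx)])
}

#' Detect candidate variant sites from pileup columns
#'
#' Emits one candidate per column whose base evidence — coverage, count and
#' frequency of the alternative allele — meets the thresholds (all
#' inclusive, "at least"). The alternative allele is the non-reference base
#' with the highest count; ties are broken by the fixed base order
#' A < C < G < T.
#'
#' @param columns pileup tibble from [pileup()].
#' @param min_depth minimum read coverage (default 10).
#' @param min_alt minimum reads supporting the alternative allele (default 2).
#' @param min_alt_fraction minimum alternative-allele fraction (default
#'   0.05); keeps a fixed 2-read count rule from admitting paired
#'   sequencing errors at high coverage.
#' @param sample optional sample id attached to candidates.
#' @return tibble with `sample`, `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `mismatch_type` (e.g. `"A>G"`).
#' @export
detect_candidates <- function(columns, min_depth = 10L, min_alt = 2L,
                              min_alt_fraction = 0.05,
                              sample = NA_character_) {
  if (!nrow(columns)) {
    return(tibble(sample = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), depth = integer(),
                  alt_count = integer(), mismatch_type = character()))
  }
  ac <- alt_counts(columns)
  out <- dplyr::bind_cols(columns[, c("chrom", "pos", "ref", "depth")], ac)
  out <- out[out$depth >= min_depth & out$alt_count >= min_alt &
               out$alt_count / out$depth >= min_alt_fraction, ]
  out |>
    dplyr::mutate(sample = sample,
                  mismatch_type = paste0(.data$ref, ">", .data$alt)) |>
    dplyr::select("sample", "chrom", "pos", "ref", "alt", "depth",
                  "alt_count", "mismatch_type")
}

#' Call germline DNA variants from the pooled DNA pileup
#'
#' A position is reported as a DNA variant when its alternative-allele
#' fraction, support and coverage all reach their thresholds; zygosity is
#' `het` below `hom_fraction`, `hom` at or above it.
#'
#' @param dna_columns pileup tibble from the pooled DNA sample.
#' @param min_fraction minimum DNA alt fraction (default 0.1).
#' @param min_alt minimum alt reads (default 2).
#' @param min_depth minimum coverage (default 10).
#' @param hom_fraction alt fraction at/above which a call is `hom`
#'   (default 0.9).
#' @return known-variant tibble (`chrom`, `pos`, `ref`, `alt`, `zygosity`).
#' @export
call_dna_variants <- function(dna_columns, min_fraction = 0.1, min_alt = 2L,
                              min_depth = 10L, hom_fraction = 0.9) {
  if (!nrow(dna_columns)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), zygosity = character()))
  }
  ac <- alt_counts(dna_columns)
  out <- dplyr::bind_cols(dna_columns[, c("chrom", "pos", "ref", "depth")], ac)
  out |>
    dplyr::mutate(fraction = .data$alt_count / .data$depth) |>
    dplyr::filter(.data$depth >= min_depth, .data$alt_count >= min_alt,
                  .data$fraction >= min_fraction) |>
    dplyr::mutate(zygosity = ifelse(.data$fraction >= hom_fraction,
                                    "hom", "het")) |>
    dplyr::select("chrom", "pos", "ref", "alt", "zygosity")
}

# gene bodies: transcript span including introns
gene_bodies <- function(models) {
  models |>
    dplyr::group_by(.data$chrom, .data$gene_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}

#' Apply the annotation/DNA filtration cascade to candidate sites
#'
#' Each candidate is annotated with the full trail of failed filters, applied
#' as independent predicates: (1) DNA-variant positions, (2) known SNPs,
#' (3) intergenic positions (outside every transcript span, introns
#' retained), (4) reference homopolymer runs longer than 5 nt, (5) simple
#' repeat intervals. Because each filter is a pure positional predicate, the
#' surviving set does not depend on the order of application.
#'
#' @param cands candidate tibble from [detect_candidates()].
#' @param dna_vars DNA-variant tibble from [call_dna_variants()].
#' @param known_snps known-SNP tibble (see [read_known_variants()]).
#' @param models gene-model tibble (see [read_gtf()]).
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param repeats repeat-interval tibble (1-based closed, see [read_bed()]).
#' @return tibble of editing calls: candidate columns plus `filter_trail`
#'   (semicolon-joined failed filters, `""` if none), `status`
#'   (`"survivor"`/`"filtered"`) and `cluster_id` (`NA`, set later by
#'   [cluster_call()]).
#' @export
filtration_cascade <- function(cands, dna_vars, known_snps, models, genome,
                               repeats) {
  for (nm in c("dna_vars", "known_snps", "models", "repeats")) {
    if (is.null(get(nm))) abort(sprintf("filter resource '%s' is missing", nm))
  }
  bodies <- gene_bodies(models)
  key <- function(tbl) paste(tbl$chrom, tbl$pos)
  in_intervals <- function(chrom, pos, iv) {
    if (!nrow(iv)) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      sub <- iv[iv$chrom == ch, ]
      if (!nrow(sub)) next
      out[i] <- vapply(pos[i], function(p) any(sub$start <= p & sub$end >= p),
                       logical(1))
    }
    out
  }
  chrom_str <- stats::setNames(
    lapply(names(genome), function(ch) as.character(genome[[ch]])),
    names(genome)
  )
  fails <- list(
    dna_variant = key(cands) %in% key(dna_vars),
    known_snp = key(cands) %in% key(known_snps),
    intergenic = !in_intervals(cands$chrom, cands$pos, bodies),
    homopolymer = unname(mapply(function(ch, p)
      homopolymer_run_at(chrom_str[[ch]], p) >= 6L, cands$chrom, cands$pos)),
    simple_repeat = in_intervals(cands$chrom, cands$pos, repeats)
  )
  fail_mat <- do.call(cbind, fails)
  trail <- apply(fail_mat, 1, function(f)
    paste(names(fails)[f], collapse = ";"))
  cands |>
    dplyr::mutate(
      filter_trail = if (nrow(cands)) trail else character(0),
      status = ifelse(.data$filter_trail == "", "survivor", "filtered"),
      cluster_id = NA_character_
    )
}

#' Cluster-based editing calling
#'
#' Within each chromosome, surviving candidates of the same mismatch type are
#' single-linkage clustered: consecutive same-type sites at most `window_bp`
#' apart join one cluster. Clusters with at least `min_cluster` members are
#' called; a lone site is rescued only when its alternative-allele fraction
#' reaches `lone_site_min_fraction`, otherwise it is filtered as
#' `no_cluster_support`. Clustered same-type sites are the hallmark of ADAR
#' hyper-editing that this step exploits.
#'
#' @param survivors output of [filtration_cascade()] (only rows with
#'   `status == "survivor"` are clustered; others pass through unchanged).
#' @param window_bp single-linkage distance (default 200).
#' @param min_cluster minimum cluster size to call (default 2).
#' @param lone_site_min_fraction alt-fraction rescue threshold for
#'   singleton clusters (default 0.2).
#' @return the same tibble with `status` set to `"called"`/`"filtered"` and
#'   `cluster_id` assigned for every called site.
#' @export
cluster_call <- function(survivors, window_bp = 200L, min_cluster = 2L,
                         lone_site_min_fraction = 0.2) {
  surv <- survivors[survivors$status == "survivor", ]
  rest <- survivors[survivors$status != "survivor", ]
  if (!nrow(surv)) {
    return(survivors)
  }
  surv <- surv |>
    dplyr::arrange(.data$chrom, .data$mismatch_type, .data$pos) |>
    dplyr::group_by(.data$chrom, .data$mismatch_type) |>
    dplyr::mutate(
      .new = c(TRUE, diff(.data$pos) > window_bp),
      .cl = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chrom, .data$mismatch_type, .data$.cl) |>
    dplyr::mutate(
      .size = dplyr::n(),
      cluster_id = sprintf("%s_%s_c%d", .data$chrom,
                           sub(">", "", .data$mismatch_type), .data$.cl),
      status = dplyr::case_when(
        .data$.size >= min_cluster ~ "called",
        .data$alt_count / .data$depth >= lone_site_min_fraction ~ "called",
        TRUE ~ "filtered"
      ),
      filter_trail = ifelse(.data$status == "filtered",
                            "no_cluster_support", .data$filter_trail),
      cluster_id = ifelse(.data$status == "called", .data$cluster_id,
                          NA_character_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".new", -".cl", -".size")
  dplyr::bind_rows(surv, rest) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Run the full per-sample calling cascade
#'
#' Convenience wrapper: duplicate marking, pileup, candidate detection,
#' filtration and cluster calling for one sample's reads.
#'
#' @param reads one sample's aligned-read tibble.
#' @param genome,models,repeats,known_snps filter resources.
#' @param dna_vars DNA-variant tibble from [call_dna_variants()].
#' @param min_mapq,min_depth,min_alt,min_alt_fraction,window_bp,min_cluster,lone_site_min_fraction
#'   thresholds passed through to the stages.
#' @return editing-call tibble (see [cluster_call()]).
#' @export
call_editing_sites <- function(reads, genome, models, repeats, known_snps,
                               dna_vars, min_mapq = 20L, min_depth = 10L,
                               min_alt = 2L, min_alt_fraction = 0.05,
                               window_bp = 200L, min_cluster = 2L,
                               lone_site_min_fraction = 0.2) {
  smp <- unique(reads$sample)
  if (length(smp) != 1L) abort("call_editing_sites() expects one sample")
  marked <- mark_duplicates(reads)
  cols <- pileup(marked, genome, min_mapq = min_mapq)
  cands <- detect_candidates(cols, min_depth = min_depth, min_alt = min_alt,
                             min_alt_fraction = min_alt_fraction,
                             sample = smp)
  filt <- filtration_cascade(cands, dna_vars, known_snps, models, genome,
                             repeats)
  cluster_call(filt, window_bp = window_bp, min_cluster = min_cluster,
               lone_site_min_fraction = lone_site_min_fraction)
}

#' Mismatch-type spectrum of called sites
#'
#' Tallies the 12 possible ref-to-alt mismatch types among called sites,
#' reporting the canonical fraction (A>G plus T>C, the ADAR signature read
#' on either strand) and, among non-canonical events, the combined share of
#' G>A and C>T.
#'
#' @param calls editing-call tibble (only `status == "called"` rows are
#'   used).
#' @return list with `spectrum` (tibble `mismatch_type`, `n`, `fraction`,
#'   `canonical`), `canonical_fraction` and `noncanonical_ga_ct_share`.
#' @export
mismatch_spectrum <- function(calls) {
  called <- calls[calls$status == "called", ]
  if (!nrow(called)) {
    return(list(spectrum = tibble(mismatch_type = character(), n = integer(),
                                  fraction = numeric(), canonical = logical()),
                canonical_fraction = NA_real_,
                noncanonical_ga_ct_share = NA_real_))
  }
  canon <- c("A>G", "T>C")
  spec <- called |>
    dplyr::count(.data$mismatch_type, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  canonical = .data$mismatch_type %in% canon) |>
    dplyr::arrange(dplyr::desc(.data$n))
  noncanon <- spec[!spec$canonical, ]
  list(
    spectrum = spec,
    canonical_fraction = sum(spec$fraction[spec$canonical]),
    noncanonical_ga_ct_share = if (nrow(noncanon) && sum(noncanon$n) > 0) {
      sum(noncanon$n[noncanon$mismatch_type %in% c("G>A", "C>T")]) /
        sum(noncanon$n)
    } else NA_real_
  )
}

#' Fraction of canonical sites arranged in hyper-editing clusters
#'
#' Computes the fraction of called canonical (A>G / T>C) sites that lie in a
#' maximal same-type group of at least `min_sites` sites in which
#' consecutive sites are at most `window_bp` apart.
#'
#' @param calls editing-call tibble.
#' @param window_bp maximum gap between consecutive clustered sites
#'   (default 100).
#' @param min_sites minimum group size (default 3).
#' @return a single proportion in `[0, 1]` (0 when there are no canonical
#'   called sites).
#' @export
cluster_characterization <- function(calls, window_bp = 100L, min_sites = 3L) {
  canon <- calls[calls$status == "called" &
                   calls$mismatch_type %in% c("A>G", "T>C"), ]
  if (!nrow(canon)) return(0)
  grouped <- canon |>
    dplyr::arrange(.data$chrom, .data$mismatch_type, .data$pos) |>
    dplyr::group_by(.data$chrom, .data$mismatch_type) |>
    dplyr::mutate(.grp = cumsum(c(TRUE, diff(.data$pos) > window_bp))) |>
    dplyr::group_by(.data$chrom, .data$mismatch_type, .data$.grp) |>
    dplyr::mutate(.gsize = dplyr::n()) |>
    dplyr::ungroup()
  mean(grouped$.gsize >= min_sites)
}
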