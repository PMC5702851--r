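# Master-list recalling of editing degrees, group means, variation
# classification, region/codon annotation, and validation FDR arithmetic.

#' Combine per-sample editing calls into a master site list
#'
#' Takes the union over samples keyed by (chrom, pos, ref, alt) of all
#' called sites, so a site called in a single sample is kept. When gene
#' models (and a genome) are supplied, region and gene annotation — and the
#' codon consequence for CDS sites — are attached once per master site.
#'
#' @param calls editing-call tibble covering one or more samples
#'   (`status == "called"` rows are used).
#' @param models optional gene-model tibble for region annotation.
#' @param genome optional [Biostrings::DNAStringSet] for codon consequences.
#' @return master-site tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `mismatch_type`, `canonical`, and (when annotated) `region`, `gene_id`,
#'   `consequence`.
#' @export
build_master_list <- function(calls, models = NULL, genome = NULL) {
  called <- calls[calls$status == "called", ]
  master <- called |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  dup_ref <- called |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_ref)) {
    abort(sprintf("conflicting reference base across samples at %s:%d",
                  dup_ref$chrom[1], dup_ref$pos[1]))
  }
  master <- master |>
    dplyr::mutate(mismatch_type = paste0(.data$ref, ">", .data$alt),
                  canonical = .data$mismatch_type %in% c("A>G", "T>C"))
  if (!is.null(models)) {
    ann <- annotate_region(master, models)
    master$region <- ann$region
    master$gene_id <- ann$gene_id
    if (!is.null(genome)) {
      master$consequence <- NA_character_
      in_cds <- which(master$region == "CDS")
      if (length(in_cds)) {
        cons <- codon_consequence(master[in_cds, ], models, genome)
        master$consequence[in_cds] <-
          paste0(cons$ref_aa, "/", ifelse(cons$alt_aa == "*", "Stop",
                                          cons$alt_aa))
      }
    }
  }
  master
}

# per-transcript feature lookup used by annotate_region/codon_consequence
transcript_spans <- function(models) {
  models |>
    dplyr::group_by(.data$chrom, .data$strand, .data$gene_id,
                    .data$transcript_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}

region_in_transcript <- function(pos, feats, strand) {
  within <- function(f) any(feats$feature == f & feats$start <= pos &
                              feats$end >= pos)
  if (within("CDS")) return("CDS")
  if (within("five_prime_utr")) return("5UTR")
  if (within("three_prime_utr")) return("3UTR")
  if (within("exon")) {
    # exon with no explicit UTR records: place relative to the CDS
    cds <- feats[feats$feature == "CDS", ]
    if (!nrow(cds)) return("exonic")
    upstream <- pos < min(cds$start)
    if (strand == "+") return(if (upstream) "5UTR" else "3UTR")
    return(if (pos > max(cds$end)) "5UTR" else "3UTR")
  }
  "intron"
}

#' Annotate sites with gene region labels
#'
#' Labels each site by its position within overlapping transcripts with
#' precedence CDS > UTR > intron inside a transcript. When overlapping
#' transcripts disagree the site is labelled `conflicting`; a site outside
#' every transcript span is `intergenic` (it should have been filtered
#' upstream, so this is a flag, not an error).
#'
#' @param sites tibble with `chrom`, `pos`.
#' @param models gene-model tibble.
#' @return tibble with `region` and `gene_id` aligned to `sites` rows.
#' @export
annotate_region <- function(sites, models) {
  spans <- transcript_spans(models)
  region <- character(nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- spans[spans$chrom == sites$chrom[i] &
                   spans$start <= sites$pos[i] & spans$end >= sites$pos[i], ]
    if (!nrow(hit)) {
      region[i] <- "intergenic"
      next
    }
    labs <- vapply(seq_len(nrow(hit)), function(k) {
      feats <- models[models$transcript_id == hit$transcript_id[k], ]
      region_in_transcript(sites$pos[i], feats, hit$strand[k])
    }, character(1))
    gene_id[i] <- hit$gene_id[1]
    region[i] <- if (length(unique(labs)) == 1L) labs[1] else "conflicting"
  }
  tibble(region = region, gene_id = gene_id)
}

# genomic positions of the CDS in coding (5'->3') order for one transcript
coding_positions <- function(feats, strand) {
  cds <- feats[feats$feature == "CDS", ]
  cds <- cds[order(cds$start), ]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(k)
    seq.int(cds$start[k], cds$end[k])), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

#' Codon consequence of an editing site in a CDS
#'
#' Rebuilds the codon containing each site on the coding strand
#' (reverse-complementing for minus-strand genes), substitutes the edited
#' base, and translates both codons with the standard genetic code.
#'
#' @param sites tibble with `chrom`, `pos`, `ref`, `alt` (reference-strand
#'   alleles), all within annotated CDS.
#' @param models gene-model tibble; CDS lengths must be multiples of 3.
#' @param genome [Biostrings::DNAStringSet] reference.
#' @return tibble with `ref_aa`, `alt_aa`, `class` in
#'   `synonymous`/`missense`/`nonsense`.
#' @export
codon_consequence <- function(sites, models, genome) {
  spans <- transcript_spans(models)
  out <- tibble(ref_aa = character(nrow(sites)),
                alt_aa = character(nrow(sites)),
                class = character(nrow(sites)))
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(sites))) {
    hit <- spans[spans$chrom == sites$chrom[i] &
                   spans$start <= sites$pos[i] & spans$end >= sites$pos[i], ]
    found <- FALSE
    for (k in seq_len(nrow(hit))) {
      feats <- models[models$transcript_id == hit$transcript_id[k], ]
      cpos <- coding_positions(feats, hit$strand[k])
      ci <- match(sites$pos[i], cpos)
      if (is.na(ci)) next
      if (length(cpos) %% 3L != 0L) {
        abort(sprintf("CDS length of %s not divisible by 3",
                      hit$transcript_id[k]))
      }
      codon_idx <- (ci - 1L) %/% 3L
      cidx <- codon_idx * 3L + 1:3
      bases <- genome_base(genome, rep(sites$chrom[i], 3), cpos[cidx])
      if (hit$strand[k] == "-") bases <- complement_base(bases)
      ref_codon <- paste(bases, collapse = "")
      alt_base <- if (hit$strand[k] == "-") complement_base(sites$alt[i]) else
        sites$alt[i]
      alt_bases <- bases
      alt_bases[ci - codon_idx * 3L] <- alt_base
      alt_codon <- paste(alt_bases, collapse = "")
      ref_aa <- unname(gc[ref_codon])
      alt_aa <- unname(gc[alt_codon])
      out$ref_aa[i] <- ref_aa
      out$alt_aa[i] <- alt_aa
      out$class[i] <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
        else if (ref_aa == alt_aa) "synonymous" else "missense"
      found <- TRUE
      break
    }
    if (!found) abort(sprintf("site %s:%d is not inside an annotated CDS",
                              sites$chrom[i], sites$pos[i]))
  }
  out
}

#' Re-evaluate editing degrees of master sites in every sample
#'
#' For every master site and sample, recomputes the editing degree as the
#' ratio of reads supporting the edited base to the total reads covering the
#' site, from that sample's duplicate-marked, mapping-quality-filtered
#' pileup. Samples covering a site below `recall_min_depth` are marked
#' missing (`NA`).
#'
#' @param master master-site tibble from [build_master_list()].
#' @param reads aligned-read tibble over all samples (column `sample`).
#' @param genome [Biostrings::DNAStringSet] reference.
#' @param recall_min_depth minimum coverage for a usable degree (default 5).
#' @param min_mapq minimum mapping quality (default 20).
#' @return long tibble: master keys plus `sample`, `depth`, `degree`.
#' @export
recall_degrees <- function(master, reads, genome, recall_min_depth = 5L,
                           min_mapq = 20L) {
  keys <- master[, c("chrom", "pos", "ref", "alt")]
  out <- list()
  for (smp in unique(reads$sample)) {
    r <- reads[reads$sample == smp, ]
    # only reads that can overlap a master site feed the pileup
    keep <- rep(FALSE, nrow(r))
    for (ch in unique(keys$chrom)) {
      s <- sort(keys$pos[keys$chrom == ch])
      i <- which(r$chrom == ch)
      if (!length(s) || !length(i)) next
      ends <- r$pos[i] + nchar(r$seq[i]) - 1L
      keep[i] <- findInterval(ends, s) > findInterval(r$pos[i] - 1L, s)
    }
    cols <- pileup(r[keep, ], genome, min_mapq = min_mapq)
    prof <- keys |>
      dplyr::left_join(cols, by = c("chrom", "pos"),
                       suffix = c("", ".pile")) |>
      dplyr::mutate(
        depth = dplyr::coalesce(.data$depth, 0L),
        alt_n = dplyr::case_when(
          .data$alt == "A" ~ .data$A, .data$alt == "C" ~ .data$C,
          .data$alt == "G" ~ .data$G, TRUE ~ .data$T
        ),
        degree = ifelse(.data$depth >= recall_min_depth,
                        dplyr::coalesce(.data$alt_n, 0L) / .data$depth,
                        NA_real_),
        sample = smp
      ) |>
      dplyr::select("chrom", "pos", "ref", "alt", "sample", "depth",
                    "degree")
    out[[smp]] <- prof
  }
  dplyr::bind_rows(out)
}

#' Group-mean editing degrees
#'
#' Averages per-sample editing degrees over the available (non-missing)
#' replicates of each group and spreads groups into columns.
#'
#' @param profiles long degree tibble from [recall_degrees()].
#' @param groups tibble mapping `sample` to `group` (this is also where,
#'   e.g., two dose arms of the same drug are merged into one group).
#' @return wide tibble: `chrom`, `pos`, `ref`, `alt` plus one mean-degree
#'   column per group (`NA` when no replicate had usable depth).
#' @export
group_mean_degrees <- function(profiles, groups) {
  missing <- setdiff(unique(profiles$sample), groups$sample)
  if (length(missing)) {
    abort(sprintf("sample(s) without a group: %s",
                  paste(missing, collapse = ", ")))
  }
  profiles |>
    dplyr::inner_join(groups, by = "sample") |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$group) |>
    dplyr::summarise(
      mean_degree = if (all(is.na(.data$degree))) NA_real_ else
        mean(.data$degree, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_degree")
}

#' Classify editing-degree variation between treatments and control
#'
#' Computes, per site, the change in group-mean editing degree of every
#' treatment relative to control (treatment minus control). A site is
#' labelled `high` when the absolute change exceeds `high_thresh` in every
#' treatment, `low` when it stays below `low_thresh` in every treatment,
#' and `intermediate` otherwise. High sites with deltas of mixed sign are
#' `discordant` and excluded from the up/down tallies.
#'
#' @param means wide group-mean tibble (one column per group, degrees as
#'   proportions in `[0, 1]`), e.g. from [group_mean_degrees()].
#' @param control name of the control column (default `"control"`).
#' @param treatments treatment column names; default: every group column
#'   other than the control that is present in `means`.
#' @param high_thresh,low_thresh classification thresholds on the absolute
#'   change (defaults 0.15 and 0.05).
#' @return `means` plus `delta_<treatment>` columns, `label`
#'   (`high`/`low`/`intermediate`) and `direction`
#'   (`up`/`down`/`discordant`/`n/a`).
#' @export
classify_variation <- function(means, control = "control", treatments = NULL,
                               high_thresh = 0.15, low_thresh = 0.05) {
  if (!control %in% names(means)) {
    abort(sprintf("control column '%s' not found", control))
  }
  treatments <- treatments %||%
    setdiff(names(means)[vapply(means, is.numeric, logical(1))],
            c(control, "pos"))
  if (!length(treatments)) abort("no treatment groups to compare")
  deltas <- lapply(treatments, function(t) means[[t]] - means[[control]])
  names(deltas) <- treatments
  dmat <- do.call(cbind, deltas)
  all_high <- apply(abs(dmat) > high_thresh, 1, all)
  all_low <- apply(abs(dmat) < low_thresh, 1, all)
  label <- dplyr::case_when(
    apply(is.na(dmat), 1, any) ~ NA_character_,
    all_high ~ "high",
    all_low ~ "low",
    TRUE ~ "intermediate"
  )
  direction <- dplyr::case_when(
    is.na(label) | label != "high" ~ "n/a",
    apply(dmat > 0, 1, all) ~ "up",
    apply(dmat < 0, 1, all) ~ "down",
    TRUE ~ "discordant"
  )
  out <- means
  for (t in treatments) out[[paste0("delta_", t)]] <- deltas[[t]]
  out$label <- label
  out$direction <- direction
  out
}

#' Summarise a variation classification
#'
#' @param classes output of [classify_variation()], optionally carrying a
#'   `gene_id` column.
#' @return one-row tibble with `n_sites`, `n_high`, `n_up`, `n_down`,
#'   `n_discordant`, `n_low`, `n_intermediate` and (when genes are known)
#'   `n_genes_high`. The up/down/discordant counts partition `n_high`.
#' @export
variation_summary <- function(classes) {
  high <- classes[!is.na(classes$label) & classes$label == "high", ]
  out <- tibble(
    n_sites = nrow(classes),
    n_high = nrow(high),
    n_up = sum(high$direction == "up"),
    n_down = sum(high$direction == "down"),
    n_discordant = sum(high$direction == "discordant"),
    n_low = sum(classes$label == "low", na.rm = TRUE),
    n_intermediate = sum(classes$label == "intermediate", na.rm = TRUE)
  )
  if ("gene_id" %in% names(classes)) {
    out$n_genes_high <- dplyr::n_distinct(high$gene_id)
  }
  out
}

#' Validation false-discovery rate
#'
#' The fraction of assessed sites failing orthogonal (Sanger) validation,
#' as a percentage.
#'
#' @param n_assessed,n_failed validated-site tallies (vectorised).
#' @return `100 * n_failed / n_assessed`, unrounded.
#' @export
validation_fdr <- function(n_assessed, n_failed) {
  if (any(n_assessed <= 0)) abort("n_assessed must be positive")
  if (any(n_failed < 0 | n_failed > n_assessed)) {
    abort("n_failed must lie in [0, n_assessed]")
  }
  100 * n_failed / n_assessed
}

#' Integer-truncated percentage
#'
#' Report-style percentage truncated toward zero (so 333/762 prints as 43).
#'
#' @param numerator,denominator counts.
#' @return truncated integer percentage.
#' @export
truncated_percent <- function(numerator, denominator) {
  trunc(100 * numerator / denominator)
}
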