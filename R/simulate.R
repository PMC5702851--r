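# Synthetic editome generator: genomes, gene models, planted editing truth,
# decoys, and pre-aligned reads. Reads are emitted wholly within single exons
# with match-only alignments, so no aligner (and no splice-aware CIGAR) is
# needed downstream; the pipeline's computation starts at the pileup.

#' Simulate a reference genome, gene models, decoys and planted truth
#'
#' Generates a random genome, places non-overlapping genes with exon/intron
#' structure and UTR/CDS annotation on alternating strands, plants homopolymer
#' runs (length >= 6) and simple tandem repeats inside gene bodies as decoys,
#' chooses clustered editing sites (A on the coding strand, so T>C on the
#' reference strand for minus-strand genes), exonic het/hom SNPs, and
#' per-condition gene abundances. All randomness is governed by
#' `config$seed`: the same config reproduces byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return a list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `models` (GTF-style tibble, see [read_gtf()]), `repeats` (BED-style
#'   tibble, 1-based closed), `truth` (list of tibbles `editing`, `snps`,
#'   `decoys`, `decoy_sites`, `expression`) and `config`.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, sim_reference_impl(config))
}

sim_reference_impl <- function(cfg) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom_str <- vapply(chroms, function(ch) {
    paste(sample(BASES, cfg$chrom_length, replace = TRUE), collapse = "")
  }, character(1))

  layout <- gene_layout(cfg, chroms)
  genes <- layout$genes

  # decoys are written into the reference inside exons, so RNA reads cover them
  dec <- plant_decoys(cfg, genes, chrom_str)
  chrom_str <- dec$chrom_str

  edits <- plant_editing_sites(cfg, genes, chrom_str, dec$decoys)
  snps <- plant_snps(cfg, genes, chrom_str, edits, dec$decoys)
  expr <- plant_expression(cfg, genes)

  genome <- Biostrings::DNAStringSet(chrom_str)
  names(genome) <- chroms

  list(
    genome = genome,
    models = build_models(genes, cfg),
    repeats = dec$decoys |>
      dplyr::filter(.data$kind == "simple_repeat") |>
      dplyr::select("chrom", "start", "end", "kind"),
    truth = list(editing = edits, snps = snps,
                 decoys = dec$decoys, decoy_sites = dec$decoy_sites,
                 expression = expr),
    config = cfg
  )
}

# non-overlapping genes, round-robin over chromosomes, alternating strand
gene_layout <- function(cfg, chroms) {
  span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  per_chrom <- table(factor(chroms[(seq_len(cfg$n_genes) - 1L) %%
                                     length(chroms) + 1L], levels = chroms))
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    n <- as.integer(per_chrom[[ch]])
    if (n == 0L) next
    gap <- (cfg$chrom_length - n * span) %/% (n + 1L)
    if (gap < 20L) {
      abort(sprintf("genes do not fit: %d genes of span %d on a %d bp chromosome",
                    n, span, cfg$chrom_length))
    }
    for (k in seq_len(n)) {
      gi <- gi + 1L
      gstart <- gap + (k - 1L) * (span + gap) + 1L
      rows[[gi]] <- tibble(
        gene_id = sprintf("gene%02d", gi),
        transcript_id = sprintf("gene%02d.t1", gi),
        chrom = ch,
        strand = if (gi %% 2L == 1L) "+" else "-",
        gstart = gstart, gend = gstart + span - 1L
      )
    }
  }
  list(genes = dplyr::bind_rows(rows), span = span)
}

gene_exons <- function(gene, cfg) {
  j <- seq_len(cfg$exons_per_gene)
  estart <- gene$gstart + (j - 1L) * (cfg$exon_length + cfg$intron_length)
  tibble(j = j, estart = estart, eend = estart + cfg$exon_length - 1L)
}

# transcript-coordinate partition into 5'UTR / CDS / 3'UTR (CDS %% 3 == 0)
tx_regions <- function(cfg) {
  L <- cfg$exons_per_gene * cfg$exon_length
  u5 <- round(L * cfg$utr5_fraction)
  u3 <- round(L * cfg$utr3_fraction)
  cds <- L - u5 - u3
  u5 <- u5 + cds %% 3L   # keep the CDS a whole number of codons
  cds <- L - u5 - u3
  list(L = L, utr5 = c(1L, u5), cds = c(u5 + 1L, u5 + cds),
       utr3 = c(u5 + cds + 1L, L))
}

# map a transcript-coordinate interval to genomic intervals (1-based closed)
tx_to_genomic <- function(lo, hi, exons, strand, exon_length) {
  k <- nrow(exons)
  out <- list()
  for (j in seq_len(k)) {
    tx_lo <- if (strand == "+") (j - 1L) * exon_length + 1L else
      (k - j) * exon_length + 1L
    tx_hi <- tx_lo + exon_length - 1L
    o_lo <- max(lo, tx_lo); o_hi <- min(hi, tx_hi)
    if (o_lo > o_hi) next
    if (strand == "+") {
      g_lo <- exons$estart[j] + (o_lo - tx_lo)
      g_hi <- exons$estart[j] + (o_hi - tx_lo)
    } else {
      g_hi <- exons$eend[j] - (o_lo - tx_lo)
      g_lo <- exons$eend[j] - (o_hi - tx_lo)
    }
    out[[length(out) + 1L]] <- tibble(start = g_lo, end = g_hi, exon = j)
  }
  dplyr::bind_rows(out)
}

build_models <- function(genes, cfg) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    exons <- gene_exons(g, cfg)
    reg <- tx_regions(cfg)
    feat <- function(feature, lo, hi) {
      iv <- tx_to_genomic(lo, hi, exons, g$strand, cfg$exon_length)
      tibble(chrom = g$chrom, source = "editomer_sim", feature = feature,
             start = iv$start, end = iv$end, score = ".", strand = g$strand,
             frame = ".", gene_id = g$gene_id, transcript_id = g$transcript_id)
    }
    ex <- tibble(chrom = g$chrom, source = "editomer_sim", feature = "exon",
                 start = exons$estart, end = exons$eend, score = ".",
                 strand = g$strand, frame = ".", gene_id = g$gene_id,
                 transcript_id = g$transcript_id)
    cds <- feat("CDS", reg$cds[1], reg$cds[2])
    # GTF frame: bases to skip to reach the first complete codon, in coding order
    cds_tx <- tx_to_genomic(reg$cds[1], reg$cds[2], exons, g$strand,
                            cfg$exon_length)
    ord <- if (g$strand == "+") order(cds_tx$start) else order(-cds_tx$start)
    lens <- cds_tx$end - cds_tx$start + 1L
    cum <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
    frame <- (3L - cum %% 3L) %% 3L
    cds$frame[ord] <- as.character(frame)
    rows[[i]] <- dplyr::bind_rows(
      ex, cds,
      feat("five_prime_utr", reg$utr5[1], reg$utr5[2]),
      feat("three_prime_utr", reg$utr3[1], reg$utr3[2])
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$start, .data$feature)
}

plant_decoys <- function(cfg, genes, chrom_str) {
  used <- tibble(chrom = character(), start = integer(), end = integer())
  decoys <- list()
  decoy_sites <- list()
  n_total <- cfg$n_homopolymer_decoys + cfg$n_repeat_decoys
  if (n_total == 0L) {
    return(list(chrom_str = chrom_str,
                decoys = tibble(chrom = character(), start = integer(),
                                end = integer(), kind = character()),
                decoy_sites = tibble(chrom = character(), pos = integer(),
                                     ref = character(), alt = character())))
  }
  kinds <- c(rep("homopolymer", cfg$n_homopolymer_decoys),
             rep("simple_repeat", cfg$n_repeat_decoys))
  for (d in seq_len(n_total)) {
    kind <- kinds[d]
    len <- if (kind == "homopolymer") sample(6:9, 1) else 30L
    placed <- FALSE
    for (try in 1:50) {
      g <- genes[sample.int(nrow(genes), 1), ]
      exons <- gene_exons(g, cfg)
      e <- exons[sample.int(nrow(exons), 1), ]
      start <- e$estart + sample.int(cfg$exon_length - len - 40L, 1) + 20L
      end <- start + len - 1L
      clash <- any(used$chrom == g$chrom & used$start <= end + 10L &
                     used$end >= start - 10L)
      if (clash) next
      seqrep <- if (kind == "homopolymer") {
        strrep(sample(BASES, 1), len)
      } else {
        strrep(sample(c("AC", "AG", "CT", "GT"), 1), len / 2L)
      }
      stringr::str_sub(chrom_str[[g$chrom]], start, end) <- seqrep
      used <- dplyr::bind_rows(used, tibble(chrom = g$chrom, start = start,
                                            end = end))
      decoys[[d]] <- tibble(chrom = g$chrom, start = start, end = end,
                            kind = kind)
      # plant RNA-only mismatches inside the decoy so filters are exercised
      dp <- unique(start + sample.int(len, 2, replace = TRUE) - 1L)
      dref <- stringr::str_sub(chrom_str[[g$chrom]], dp, dp)
      decoy_sites[[d]] <- tibble(chrom = g$chrom, pos = dp, ref = dref,
                                 alt = transition_of(dref))
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place decoys; genome too crowded")
  }
  list(chrom_str = chrom_str, decoys = dplyr::bind_rows(decoys),
       decoy_sites = dplyr::bind_rows(decoy_sites))
}

transition_of <- function(b) chartr("ACGT", "GTAC", b)

# clustered editing sites: A on the coding strand, mostly in the 3'UTR
plant_editing_sites <- function(cfg, genes, chrom_str, decoys) {
  if (cfg$n_edit_clusters == 0L) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  ref = character(), alt = character(), cluster = character(),
                  region = character(), gene_id = character()))
  }
  reg <- tx_regions(cfg)
  used_pos <- list()
  rows <- list()
  gene_order <- rep(sample.int(nrow(genes)), length.out = cfg$n_edit_clusters)
  for (ci in seq_len(cfg$n_edit_clusters)) {
    placed <- FALSE
    for (try in 1:60) {
      g <- genes[if (try == 1) gene_order[ci] else sample.int(nrow(genes), 1), ]
      exons <- gene_exons(g, cfg)
      region <- if (stats::runif(1) < cfg$utr3_site_fraction) "utr3" else "cds"
      segs <- tx_to_genomic(reg[[region]][1], reg[[region]][2], exons,
                            g$strand, cfg$exon_length)
      segs <- segs[segs$end - segs$start + 1L >= cfg$cluster_span + 20L, ]
      if (!nrow(segs)) next
      seg <- segs[which.max(segs$end - segs$start), ]
      # clip to the exon core: without junction reads, coverage decays within
      # one read length of an exon edge, so sites there would be under-covered
      ex <- exons[exons$j == seg$exon, ]
      core_lo <- max(seg$start + 10L, ex$estart + cfg$read_length)
      core_hi <- min(seg$end - 10L, ex$eend - cfg$read_length)
      if (core_hi - core_lo + 1L < cfg$cluster_span + 10L) next
      cand <- candidate_a_positions(chrom_str[[g$chrom]], core_lo, core_hi,
                                    g$strand)
      cand <- setdiff(cand, unlist(used_pos))
      cand <- cand[!in_any_interval(g$chrom, cand, decoys)]
      if (length(cand) < cfg$sites_per_cluster) next
      anchor <- sample(cand, 1)
      win <- cand[cand >= anchor & cand <= anchor + cfg$cluster_span]
      if (length(win) < cfg$sites_per_cluster) next
      pos <- sort(sample(win, cfg$sites_per_cluster))
      ref <- stringr::str_sub(chrom_str[[g$chrom]], pos, pos)
      rows[[ci]] <- tibble(
        chrom = g$chrom, pos = pos, strand = g$strand, ref = ref,
        alt = ifelse(ref == "A", "G", "C"),
        cluster = sprintf("truth_c%02d", ci),
        region = if (region == "utr3") "3UTR" else "CDS",
        gene_id = g$gene_id
      )
      used_pos[[ci]] <- pos
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place editing clusters; enlarge the genome")
  }
  edits <- dplyr::bind_rows(rows)
  for (cond in names(cfg$edit_rates)) {
    edits[[paste0("rate_", cond)]] <- cfg$edit_rates[[cond]]
  }
  edits
}

# coding-strand adenosines (A on + / T on -), avoiding reference runs >= 6
candidate_a_positions <- function(chrom_seq, lo, hi, strand) {
  want <- if (strand == "+") "A" else "T"
  s <- stringr::str_sub(chrom_seq, lo, hi)
  offs <- which(strsplit(s, "", fixed = TRUE)[[1]] == want)
  pos <- lo + offs - 1L
  pos[!vapply(pos, function(p) homopolymer_run_at(chrom_seq, p) >= 6L,
              logical(1))]
}

homopolymer_run_at <- function(chrom_seq, pos) {
  b <- stringr::str_sub(chrom_seq, pos, pos)
  left <- pos
  while (left > 1L && stringr::str_sub(chrom_seq, left - 1L, left - 1L) == b) {
    left <- left - 1L
  }
  n <- nchar(chrom_seq)
  right <- pos
  while (right < n && stringr::str_sub(chrom_seq, right + 1L, right + 1L) == b) {
    right <- right + 1L
  }
  right - left + 1L
}

in_any_interval <- function(chrom, pos, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(intervals$chrom == chrom &
                                intervals$start <= p & intervals$end >= p),
         logical(1))
}

plant_snps <- function(cfg, genes, chrom_str, edits, decoys) {
  n <- cfg$n_het_snps + cfg$n_hom_snps
  if (n == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), zygosity = character()))
  }
  exon_pool <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- gene_exons(g, cfg)
    tibble(chrom = g$chrom, start = ex$estart, end = ex$eend)
  }))
  pool <- dplyr::bind_rows(lapply(seq_len(nrow(exon_pool)), function(i) {
    tibble(chrom = exon_pool$chrom[i],
           pos = seq(exon_pool$start[i] + 5L, exon_pool$end[i] - 5L))
  }))
  taken <- paste(edits$chrom, edits$pos)
  pool <- pool[!paste(pool$chrom, pool$pos) %in% taken, ]
  keep <- !mapply(function(ch, p) any(decoys$chrom == ch & decoys$start <= p &
                                        decoys$end >= p),
                  pool$chrom, pool$pos)
  pool <- pool[keep, ]
  idx <- sample.int(nrow(pool), n)
  snps <- pool[idx, ]
  snps$ref <- mapply(function(ch, p) stringr::str_sub(chrom_str[[ch]], p, p),
                     snps$chrom, snps$pos)
  snps$alt <- vapply(snps$ref, function(r) sample(setdiff(BASES, r), 1),
                     character(1))
  snps$zygosity <- c(rep("het", cfg$n_het_snps), rep("hom", cfg$n_hom_snps))
  dplyr::arrange(snps, .data$chrom, .data$pos)
}

plant_expression <- function(cfg, genes) {
  n <- nrow(genes)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
  n_down <- round(n * cfg$expr_frac_down)
  n_up <- round(n * cfg$expr_frac_up)
  class <- sample(c(rep("down", n_down), rep("up", n_up),
                    rep("none", n - n_down - n_up)))
  expr <- tibble(gene_id = genes$gene_id, class = class)
  conds <- names(cfg$edit_rates)
  control <- conds[1]
  expr[[paste0("rel_", control)]] <- base
  for (cond in setdiff(conds, control)) {
    fold <- stats::runif(n, cfg$expr_fold_range[1], cfg$expr_fold_range[2])
    expr[[paste0("rel_", cond)]] <- dplyr::case_when(
      class == "down" ~ base / fold,
      class == "up" ~ base * fold,
      TRUE ~ base
    )
  }
  expr
}

#' Simulate pre-aligned RNA-seq and DNA-seq reads with planted truth
#'
#' RNA reads are drawn per sample from exons in proportion to the gene's
#' planted abundance; at each planted editing site every overlapping RNA read
#' carries the edited base independently with the condition's true rate. DNA
#' reads never carry edited bases but carry SNP alleles (het at ~0.5, hom at
#' 1.0, in RNA as well). A configurable fraction of RNA fragments is
#' duplicated. Reads are emitted pre-aligned (match-only CIGAR) and sorted by
#' coordinate.
#'
#' @param reference output of [simulate_reference()].
#' @param config a [sim_config()]; defaults to the one inside `reference`.
#' @return list with tibbles `rna` (all samples, see [read_sam()] for
#'   columns) and `dna` (one pooled sample named `dna_pool`).
#' @export
simulate_reads <- function(reference, config = reference$config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L, sim_reads_impl(reference, config))
}

sim_reads_impl <- function(ref, cfg) {
  chrom_str <- vapply(names(ref$genome), function(ch)
    as.character(ref$genome[[ch]]), character(1))
  genes <- gene_layout(cfg, names(ref$genome))$genes
  truth <- ref$truth
  conds <- names(cfg$edit_rates)
  control <- conds[1]

  # per-condition RNA variant tables: editing + decoy mismatches + SNPs
  rna_vars <- function(cond) {
    dplyr::bind_rows(
      tibble(chrom = truth$editing$chrom, pos = truth$editing$pos,
             alt = truth$editing$alt,
             rate = truth$editing[[paste0("rate_", cond)]]),
      if (nrow(truth$decoy_sites)) {
        tibble(chrom = truth$decoy_sites$chrom, pos = truth$decoy_sites$pos,
               alt = truth$decoy_sites$alt, rate = cfg$decoy_mismatch_rate)
      },
      tibble(chrom = truth$snps$chrom, pos = truth$snps$pos,
             alt = truth$snps$alt,
             rate = ifelse(truth$snps$zygosity == "hom", 1.0, 0.5))
    )
  }
  dna_vars <- tibble(chrom = truth$snps$chrom, pos = truth$snps$pos,
                     alt = truth$snps$alt,
                     rate = ifelse(truth$snps$zygosity == "hom", 1.0, 0.5))

  rel <- truth$expression
  rl <- cfg$read_length
  qual <- strrep("F", rl)

  sample_tbl <- tidyr::crossing(
    group = names(cfg$groups)
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(reps = list(seq_len(cfg$groups[[.data$group]]))) |>
    tidyr::unnest("reps") |>
    dplyr::mutate(sample = sprintf("%s_rep%d", .data$group, .data$reps))

  rna <- dplyr::bind_rows(lapply(seq_len(nrow(sample_tbl)), function(si) {
    grp <- sample_tbl$group[si]
    smp <- sample_tbl$sample[si]
    ab <- rel[[paste0("rel_", grp)]]
    cov <- cfg$rna_depth * ab / mean(ab)
    reads <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(gi) {
      g <- genes[gi, ]
      exons <- gene_exons(g, cfg)
      txlen <- cfg$exons_per_gene * cfg$exon_length
      n <- stats::rpois(1, cov[gi] * txlen / rl)
      if (n == 0L) return(NULL)
      ej <- sample.int(nrow(exons), n, replace = TRUE)
      start <- exons$estart[ej] + sample.int(cfg$exon_length - rl + 1L, n,
                                             replace = TRUE) - 1L
      tibble(chrom = g$chrom, pos = start)
    }))
    finalize_reads(reads, smp, chrom_str, rna_vars(grp), cfg,
                   duplicates = TRUE)
  }))

  dna_reads <- dplyr::bind_rows(lapply(names(ref$genome), function(ch) {
    len <- nchar(chrom_str[[ch]])
    n <- stats::rpois(1, cfg$dna_depth * len / rl)
    tibble(chrom = ch, pos = sample.int(len - rl + 1L, n, replace = TRUE))
  }))
  dna <- finalize_reads(dna_reads, "dna_pool", chrom_str, dna_vars, cfg,
                        duplicates = FALSE)

  list(rna = rna, dna = dna)
}

# attach sequence, alleles, errors, mapq, mates, duplicates; sort by coordinate
finalize_reads <- function(reads, sample, chrom_str, vars, cfg, duplicates) {
  rl <- cfg$read_length
  n <- nrow(reads)
  if (n == 0L) abort("no reads generated; raise depth")
  seqs <- character(n)
  for (ch in unique(reads$chrom)) {
    i <- which(reads$chrom == ch)
    seqs[i] <- stringr::str_sub(chrom_str[[ch]], reads$pos[i],
                                reads$pos[i] + rl - 1L)
  }
  # planted alleles: per overlapping read, Bernoulli(rate)
  for (vi in seq_len(nrow(vars))) {
    i <- which(reads$chrom == vars$chrom[vi] &
                 reads$pos <= vars$pos[vi] & reads$pos > vars$pos[vi] - rl)
    if (!length(i)) next
    hit <- i[stats::runif(length(i)) < vars$rate[vi]]
    off <- vars$pos[vi] - reads$pos[hit] + 1L
    for (k in seq_along(hit)) {
      substr(seqs[hit[k]], off[k], off[k]) <- vars$alt[vi]
    }
  }
  # sequencing errors: substitute a different base
  n_err <- stats::rbinom(n, rl, cfg$base_error_rate)
  for (i in which(n_err > 0L)) {
    off <- sample.int(rl, n_err[i])
    for (o in off) {
      cur <- substr(seqs[i], o, o)
      substr(seqs[i], o, o) <- sample(setdiff(BASES, cur), 1)
    }
  }
  mapq <- ifelse(stats::runif(n) < cfg$mapq_low_fraction, cfg$mapq_low,
                 cfg$mapq_high)
  mate_pos <- reads$pos + rl + stats::rpois(n, 50)
  out <- tibble(
    sample = sample,
    qname = sprintf("%s:r%06d", sample, seq_len(n)),
    flag = 0L, chrom = reads$chrom, pos = reads$pos, mapq = as.integer(mapq),
    cigar = sprintf("%dM", rl), seq = seqs, qual = strrep("F", rl),
    mate_pos = mate_pos, duplicate = FALSE
  )
  if (duplicates && cfg$duplicate_fraction > 0) {
    ndup <- stats::rbinom(1, n, cfg$duplicate_fraction)
    if (ndup > 0L) {
      di <- sample.int(n, ndup)
      dup <- out[di, ]
      dup$qname <- paste0(dup$qname, ":dup")
      out <- dplyr::bind_rows(out, dup)
    }
  }
  dplyr::arrange(out, .data$chrom, .data$pos, .data$qname)
}

#' Simulate a complete synthetic editome study
#'
#' Convenience wrapper running [simulate_reference()] then [simulate_reads()].
#'
#' @param config a [sim_config()].
#' @return the reference list with `rna` and `dna` read tibbles added.
#' @export
simulate_editome <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  reads <- simulate_reads(ref, config)
  c(ref, reads)
}

#' Write a simulated editome to disk
#'
#' Emits `genome.fa`, `models.gtf`, `repeats.bed`, `known_snps.tsv`,
#' per-sample `<sample>.sam` files, `dna_pool.sam`, and `truth_*.tsv`
#' machine-readable truth tables.
#'
#' @param sim output of [simulate_editome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_editome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genome(sim$genome, p("genome.fa"))
  write_gtf(sim$models, p("models.gtf"))
  write_bed(sim$repeats, p("repeats.bed"))
  write_known_variants(sim$truth$snps, p("known_snps.tsv"))
  for (smp in unique(sim$rna$sample)) {
    write_sam(sim$rna[sim$rna$sample == smp, ], p(paste0(smp, ".sam")),
              genome = sim$genome)
  }
  write_sam(sim$dna, p("dna_pool.sam"), genome = sim$genome)
  readr::write_tsv(sim$truth$editing, p("truth_editing.tsv"))
  readr::write_tsv(sim$truth$snps, p("truth_snps.tsv"))
  readr::write_tsv(sim$truth$decoys, p("truth_decoys.tsv"))
  readr::write_tsv(sim$truth$expression, p("truth_expression.tsv"))
  invisible(dir)
}
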