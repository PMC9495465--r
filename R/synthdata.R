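#' Default synthetic transcription-factor models
#'
#' A seeded set of synthetic PFMs for fixture generation. Each motif is 16
#' columns wide with a two-tier information profile: one very sharp "core"
#' column in the middle (counts 997/1/1/1) and fifteen strict flanking
#' columns (counts 90/3/3/3). The core column carries about 12% of the
#' motif's achievable log-odds range, so a single-base change there moves
#' the relative binding score by roughly 0.12 — across the |FIF| > 10
#' reporting gate at homotypic redundancy 1 — while a window can only reach
#' the 0.80 relative-score floor if its core base matches and at most a few
#' flank columns mismatch, which makes chance sites in random 2 kb
#' background rare (about 0.005 expected per promoter per motif, both
#' strands, at GC 0.41). Consensus sequences are drawn at random,
#' constrained to pairwise Hamming distance of at least 4 so motifs do not
#' cross-match.
#'
#' @param n_pfms Number of motifs (default 3).
#' @param width Motif width (default 16).
#' @param seed Integer seed (advances the global RNG stream).
#' @return A list of [pfm] objects (ids `SYN0001`, ..., TF names `SYNTF1`,
#'   ...), each with attribute `core_column` (the maximum-information
#'   column).
#' @export
synthetic_pfms <- function(n_pfms = 3, width = 16, seed = 1) {
  stopifnot(n_pfms >= 1, width >= 6)
  set.seed(seed)
  core <- as.integer(ceiling(width / 2))
  consensi <- character(0)
  guard <- 0L
  while (length(consensi) < n_pfms) {
    guard <- guard + 1L
    if (guard > 1000L) abort("could not draw dissimilar motif consensi")
    cand <- paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
    dists <- vapply(consensi, function(x) {
      sum(strsplit(cand, "")[[1]] != strsplit(x, "")[[1]])
    }, numeric(1))
    if (all(dists >= 4)) consensi <- c(consensi, cand)
  }
  lapply(seq_len(n_pfms), function(i) {
    counts <- matrix(3, nrow = 4, ncol = width, dimnames = list(DNA_BASES))
    cons <- strsplit(consensi[i], "")[[1]]
    for (j in seq_len(width)) counts[cons[j], j] <- 90
    counts[, core] <- 1
    counts[cons[core], core] <- 997
    p <- pfm(sprintf("SYN%04d", i), paste0("SYNTF", i), counts)
    attr(p, "core_column") <- core
    p
  })
}

#' Generate a seeded synthetic fixture with planted ground truth
#'
#' Emulates the study's inputs end to end: per gene a synthetic contig
#' carrying a 2 kb promoter of i.i.d. background at a given GC content, with
#' motif instances planted at non-overlapping offsets, SNPs of three known
#' effect classes, and accessibility peaks covering a controllable fraction
#' of the SNPs. All randomness flows from `seed`; the same seed reproduces
#' the fixture byte for byte.
#'
#' Effect classes (exact per-gene counts from `effect_mix` by
#' largest-remainder rounding, ties to the earlier class):
#'
#' * **destroyer** — a planted consensus site; the SNP sits at the motif's
#'   maximum-information column, major allele = consensus base, minor allele
#'   = the worst base there. By construction the major allele scores a
#'   relative binding score of 1 at the site and the minor allele loses
#'   affinity.
#' * **creator** — a planted near-miss site (consensus with the
#'   maximum-information column set to the worst base); the SNP's minor
#'   allele restores the consensus, so the minor allele gains affinity:
#'   the pair scores RBSm = 1 > RBS_M and the FIF is positive, past the
#'   reporting gate at homotypic redundancy 1.
#' * **neutral** — placed in background, away from all planted sites, and
#'   rejection-sampled so that no window overlapping the SNP (either allele,
#'   either strand, any PFM) reaches `rbs_floor`: "background" here means
#'   motif-free by construction, not merely on average.
#'
#' At most one site per transcription factor is planted per promoter, so the
#' planted truth implies homotypic redundancy 1 up to chance background
#' sites. Genes alternate between `+` and `-` strands so both promoter
#' orientations are exercised. Each accessible SNP gets a
#' ±`peak_halfwidth` bp accessibility peak in every requested cell line;
#' peaks are merged.
#'
#' The PWMs used for planting and for the motif-free guarantee are built
#' with `background_from_gc(gc)` — sequence background and scoring
#' background share the one GC value, so the guarantee is exact when the
#' fixture is scanned with the same background (see [run_scan()]).
#'
#' @param n_genes Number of synthetic genes.
#' @param n_snps_per_gene SNPs per promoter (default 5).
#' @param effect_mix Named proportions `destroyer`/`creator`/`neutral`
#'   summing to 1 (default `c(0.3, 0.3, 0.4)`).
#' @param length Promoter length in bp (default 2000).
#' @param gc Background GC fraction (default 0.41, human-like).
#' @param accessible_frac Fraction of SNPs covered by accessibility peaks
#'   (default 0.8; applied per SNP by a Bernoulli draw).
#' @param cell_lines Cell lines to emit tracks for (default `"Hcm"`).
#' @param pfms Motif set; default [synthetic_pfms()] seeded from `seed + 1`.
#' @param rbs_floor Relative-score floor used for the neutral motif-free
#'   guarantee (default 0.80, the pipeline's reporting floor).
#' @param maf_range Range minor-allele frequencies are drawn from (default
#'   `c(0.05, 0.5)`; all SNPs common).
#' @param peak_halfwidth Half-width of accessibility peaks in bp (default
#'   50).
#' @param seed Integer seed (required).
#' @param out_dir If non-`NULL`, write the fixture as standard files
#'   (FASTA, SNP TSV, gene TSV, one BED per cell line, JASPAR-text PFMs,
#'   truth TSV, YAML manifest) named `synthetic_*`, and include their paths
#'   in the result.
#' @return A list of class `synthetic_fixture`: `genome` (named character
#'   vector of contigs), `genes` (tibble `gene`, `chrom`, `tss`, `strand`,
#'   `length`), `snps`, `tracks`, `pfms`, `background` (the shared base
#'   probabilities), `truth` (tibble `rsid`, `gene`, `effect`, `tf`,
#'   `site_offset`, `accessible`), `params`, and `paths` when written.
#' @export
generate_fixture <- function(n_genes, n_snps_per_gene = 5,
                             effect_mix = c(destroyer = 0.3, creator = 0.3,
                                            neutral = 0.4),
                             length = 2000, gc = 0.41,
                             accessible_frac = 0.8, cell_lines = "Hcm",
                             pfms = NULL, rbs_floor = 0.80,
                             maf_range = c(0.05, 0.5),
                             peak_halfwidth = 50, seed,
                             out_dir = NULL) {
  stopifnot(n_genes >= 0, n_snps_per_gene >= 0, length >= 100,
            gc > 0, gc < 1, accessible_frac >= 0, accessible_frac <= 1)
  if (missing(seed)) abort("`seed` is required: fixtures are reproducible")
  if (abs(sum(effect_mix) - 1) > 1e-8) abort("effect_mix must sum to 1")
  if (is.null(names(effect_mix))) {
    names(effect_mix) <- c("destroyer", "creator", "neutral")
  }
  if (is.null(pfms)) pfms <- synthetic_pfms(seed = seed + 1L)
  base_probs <- background_from_gc(gc)
  pwms <- lapply(pfms, pfm_to_pwm, background = base_probs)
  w_max <- max(vapply(pfms, motif_width, integer(1)))
  counts <- largest_remainder(effect_mix, n_snps_per_gene)
  n_sites_needed <- counts[["destroyer"]] + counts[["creator"]]
  if (n_sites_needed > base::length(pfms)) {
    abort(paste0("effect mix needs ", n_sites_needed,
                 " planted sites per gene but only ", base::length(pfms),
                 " PFMs are available"))
  }
  pad <- 200L
  set.seed(seed)

  genome <- list(); gene_rows <- list(); snp_rows <- list()
  truth_rows <- list(); peak_rows <- list()
  snp_counter <- 0L

  for (gi in seq_len(n_genes)) {
    gene <- sprintf("G%02d", gi)
    chrom <- sprintf("chrS%02d", gi)
    strand <- if (gi %% 2L == 1L) "+" else "-"
    contig_len <- length + 2L * pad
    # promoter occupies genomic interval [pad, pad + length) in both cases:
    # plus strand puts the TSS just past it, minus strand just before it
    tss <- if (strand == "+") pad + length + 1L else pad
    # i.i.d. background in promoter frame (sense strand of the gene)
    prom <- sample(DNA_BASES, length, replace = TRUE, prob = base_probs)

    offsets <- plant_offsets(n_sites_needed, length, w_max)
    site_tf <- sample(seq_along(pfms), n_sites_needed)

    gene_snps <- list(); gene_truth <- list()
    k <- 0L
    for (e in c("destroyer", "creator")) {
      for (r in seq_len(counts[[e]])) {
        k <- k + 1L
        p <- pfms[[site_tf[k]]]
        wp <- motif_width(p)
        cons <- strsplit(consensus(p), "")[[1]]
        col <- max_info_column(pwms[[site_tf[k]]])
        worst <- worst_base(pwms[[site_tf[k]]], col)
        site <- cons
        if (e == "creator") site[col] <- worst   # near-miss planted
        prom[offsets[k] + seq_len(wp)] <- site
        snp_counter <- snp_counter + 1L
        rsid <- sprintf("rsS%04d", snp_counter)
        gene_snps[[base::length(gene_snps) + 1L]] <- tibble(
          rsid = rsid, offset = offsets[k] + col - 1L,
          major_local = site[col],
          minor_local = if (e == "destroyer") worst else cons[col])
        gene_truth[[base::length(gene_truth) + 1L]] <- tibble(
          rsid = rsid, gene = gene, effect = e,
          tf = p$tf_name, site_offset = offsets[k])
      }
    }
    forbidden <- unlist(lapply(seq_len(n_sites_needed), function(k) {
      (offsets[k] - w_max):(offsets[k] + 2L * w_max)
    })) %||% integer(0)
    taken <- vapply(gene_snps, function(s) s$offset, integer(1))
    for (r in seq_len(counts[["neutral"]])) {
      res <- sample_neutral(prom, pwms, forbidden, taken, length, rbs_floor)
      snp_counter <- snp_counter + 1L
      rsid <- sprintf("rsS%04d", snp_counter)
      gene_snps[[base::length(gene_snps) + 1L]] <- tibble(
        rsid = rsid, offset = res$offset,
        major_local = res$major, minor_local = res$minor)
      gene_truth[[base::length(gene_truth) + 1L]] <- tibble(
        rsid = rsid, gene = gene, effect = "neutral",
        tf = NA_character_, site_offset = NA_integer_)
      taken <- c(taken, res$offset)
    }
    prom_seq <- paste(prom, collapse = "")

    pad_l <- paste(sample(DNA_BASES, pad, replace = TRUE, prob = base_probs),
                   collapse = "")
    pad_r <- paste(sample(DNA_BASES, pad, replace = TRUE, prob = base_probs),
                   collapse = "")
    genomic_prom <- if (strand == "+") prom_seq else revcomp(prom_seq)
    genome[[chrom]] <- paste0(pad_l, genomic_prom, pad_r)

    gsnps <- dplyr::bind_rows(gene_snps)
    # promoter offset -> genomic 1-based position and genome-frame alleles
    if (strand == "+") {
      gsnps$pos <- pad + gsnps$offset + 1L
      gsnps$major <- gsnps$major_local
      gsnps$minor <- gsnps$minor_local
    } else {
      gsnps$pos <- pad + (length - gsnps$offset)
      gsnps$major <- complement_base(gsnps$major_local)
      gsnps$minor <- complement_base(gsnps$minor_local)
    }
    gsnps$chrom <- chrom
    gsnps$maf <- round(runif(nrow(gsnps), maf_range[1], maf_range[2]), 4)
    gsnps$accessible <- runif(nrow(gsnps)) < accessible_frac
    snp_rows[[gi]] <- gsnps
    truth <- dplyr::bind_rows(gene_truth)
    truth$accessible <- gsnps$accessible[match(truth$rsid, gsnps$rsid)]
    truth_rows[[gi]] <- truth
    gene_rows[[gi]] <- tibble(gene = gene, chrom = chrom, tss = tss,
                              strand = strand, length = length)
    if (any(gsnps$accessible)) {
      acc <- gsnps[gsnps$accessible, , drop = FALSE]
      peak_rows[[base::length(peak_rows) + 1L]] <- tibble(
        chrom = chrom,
        start = pmax(0L, acc$pos - 1L - as.integer(peak_halfwidth)),
        end = pmin(contig_len, acc$pos + as.integer(peak_halfwidth)))
    }
  }

  snps <- if (base::length(snp_rows)) {
    dplyr::bind_rows(snp_rows) |>
      dplyr::mutate(common = .data$maf > 0.01, population = "ALL") |>
      dplyr::select("rsid", "chrom", "pos", "major", "minor", "maf",
                    "common", "population")
  } else empty_snp_tbl()
  peaks <- if (base::length(peak_rows)) {
    merge_intervals(dplyr::bind_rows(peak_rows))
  } else tibble(chrom = character(), start = integer(), end = integer())
  # truth records actual coverage by the final merged peaks (a peak drawn
  # around one SNP may incidentally cover a neighbour)
  truth_all <- if (base::length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble(rsid = character(), gene = character(), effect = character(),
           tf = character(), site_offset = integer(), accessible = logical())
  if (nrow(truth_all)) {
    i <- match(truth_all$rsid, snps$rsid)
    truth_all$accessible <- is_accessible(peaks, snps$chrom[i], snps$pos[i])
  }
  tracks <- if (base::length(cell_lines)) {
    dplyr::bind_rows(lapply(cell_lines, function(cl) {
      dplyr::bind_cols(tibble(cell_line = rep(cl, nrow(peaks))), peaks)
    }))
  } else NULL
  if (is.null(tracks) || nrow(tracks) == 0L) {
    tracks <- tibble(cell_line = character(), chrom = character(),
                     start = integer(), end = integer())
  }

  fx <- structure(
    list(genome = if (base::length(genome)) unlist(genome) else
           setNames(character(0), character(0)),
         genes = if (base::length(gene_rows)) dplyr::bind_rows(gene_rows) else
           tibble(gene = character(), chrom = character(), tss = integer(),
                  strand = character(), length = integer()),
         snps = snps, tracks = tracks, pfms = pfms,
         background = base_probs,
         truth = truth_all,
         params = list(n_genes = n_genes, n_snps_per_gene = n_snps_per_gene,
                       effect_mix = effect_mix, length = length, gc = gc,
                       accessible_frac = accessible_frac,
                       cell_lines = cell_lines, rbs_floor = rbs_floor,
                       maf_range = maf_range,
                       peak_halfwidth = peak_halfwidth, seed = seed)),
    class = "synthetic_fixture"
  )
  if (!is.null(out_dir)) fx <- write_fixture(fx, out_dir)
  fx
}

#' Base probabilities at a given GC content
#'
#' @param gc GC fraction in (0, 1).
#' @return Named length-4 probability vector (A, C, G, T).
#' @export
background_from_gc <- function(gc) {
  setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

# exact integer split of n by proportions; ties go to the earlier class
largest_remainder <- function(props, n) {
  raw <- props * n
  base_counts <- floor(raw)
  short <- n - sum(base_counts)
  if (short > 0) {
    extra <- order(-(raw - base_counts), seq_along(raw))[seq_len(short)]
    base_counts[extra] <- base_counts[extra] + 1
  }
  setNames(as.integer(base_counts), names(props))
}

plant_offsets <- function(n_sites, prom_len, w) {
  if (n_sites == 0L) return(integer(0))
  lo <- w; hi <- prom_len - 2L * w
  for (try in seq_len(200L)) {
    cand <- sort(sample(lo:hi, n_sites))
    if (n_sites == 1L || all(diff(cand) >= 2L * w)) return(cand)
  }
  abort("motif density too high to place sites without overlap")
}

max_info_column <- function(pwm) {
  which.max(apply(pwm$weights, 2, max) - apply(pwm$weights, 2, min))
}

worst_base <- function(pwm, col) {
  DNA_BASES[which.min(pwm$weights[, col])]
}

sample_neutral <- function(prom, pwms, forbidden, taken, prom_len, rbs_floor) {
  seq_major <- paste(prom, collapse = "")
  for (try in seq_len(2000L)) {
    off <- sample.int(prom_len, 1L) - 1L
    if (off %in% forbidden || off %in% taken) next
    major <- prom[off + 1L]
    minor <- sample(setdiff(DNA_BASES, major), 1L)
    seq_minor <- seq_major
    substr(seq_minor, off + 1L, off + 1L) <- minor
    ok <- TRUE
    for (p in pwms) {
      hit <- scan_snp(p, seq_major, seq_minor, off)
      if (nrow(hit) && max(hit$rbs_major, hit$rbs_minor) >= rbs_floor) {
        ok <- FALSE; break
      }
    }
    if (ok) return(list(offset = off, major = major, minor = minor))
  }
  abort("could not place a motif-free neutral SNP; lower motif density")
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat("<synthetic_fixture> ", nrow(x$genes), " gene(s), ",
      nrow(x$snps), " SNP(s), ", base::length(x$pfms), " PFM(s), seed ",
      x$params$seed, "\n", sep = "")
  invisible(x)
}

# Write all fixture components as standard files under dir.
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  paths <- list(
    genome = file.path(dir, "synthetic_genome.fa"),
    snps = file.path(dir, "synthetic_snps.tsv"),
    genes = file.path(dir, "synthetic_genes.tsv"),
    pfms = file.path(dir, "synthetic_pfms.jaspar"),
    truth = file.path(dir, "synthetic_truth.tsv"),
    manifest = file.path(dir, "manifest.yaml"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$genome),
                              paths$genome)
  write_snp_table(fx$snps, paths$snps)
  readr::write_tsv(fx$genes, paths$genes, progress = FALSE)
  write_jaspar_pfm(fx$pfms, paths$pfms)
  readr::write_tsv(fx$truth, paths$truth, progress = FALSE)
  paths$tracks <- setNames(
    file.path(dir, paste0("synthetic_dnase_", fx$params$cell_lines, ".bed")),
    fx$params$cell_lines)
  for (cl in fx$params$cell_lines) {
    trk <- fx$tracks[fx$tracks$cell_line == cl, , drop = FALSE]
    readr::write_lines(sprintf("%s\t%d\t%d\t%s", trk$chrom, trk$start,
                               trk$end, cl),
                       paths$tracks[[cl]])
  }
  manifest <- c(fx$params[setdiff(names(fx$params), "effect_mix")],
                list(effect_mix = as.list(fx$params$effect_mix),
                     files = lapply(paths[setdiff(names(paths), "manifest")],
                                    function(p) unname(basename(p)))))
  yaml::write_yaml(manifest, paths$manifest)
  fx$paths <- paths
  fx
}
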