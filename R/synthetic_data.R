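# Synthetic-data generator with planted, recoverable structure. Every
# stochastic quantity flows from `seed`; the same config yields identical
# output. The defaults emulate the study design this package targets:
# 4 groups (WT/ISWI x F/M) with 3 replicates each, negative-binomial counts,
# an X-chromosome lncRNA dosage shift in males, per-class autosomal lncRNA
# median shifts, planted 4-fold DE mRNAs, latent-factor co-expressed
# lncRNA-mRNA pairs, and TE families with directional expression changes.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. All randomness in
#' the generator is a deterministic function of `seed`.
#'
#' @param seed Integer seed; fully determines all generated data.
#' @param chromosomes Chromosome names (defaults to the *Drosophila* arms).
#' @param chrom_length Length available per chromosome (nt); placement
#'   errors if the requested features do not fit.
#' @param n_genes_per_chrom Protein-coding genes per chromosome.
#' @param lnc_class_counts Named counts of novel lncRNAs to plant per
#'   positional class (`lincRNA`, `intronic`, `sense`, `antisense`). The
#'   default mixture (584, 254, 95, 67) reproduces the class proportions
#'   58.4/25.4/9.5/6.7% typical of the fly lncRNA complement.
#' @param te_families,n_te_per_family Transposable-element family names and
#'   instances to plant per family.
#' @param decoy_counts Named counts of discovery decoys
#'   (`single_exon`, `short`, `coding`, `homology`).
#' @param n_rep Replicates per (genotype, sex) group.
#' @param base_mean,base_mean_sdlog Per-transcript baseline mean drawn
#'   log-normal with median `base_mean` and `sdlog` spread.
#' @param dispersion Negative-binomial dispersion (variance
#'   \eqn{\mu + \alpha\mu^2}); 0 degenerates to Poisson.
#' @param lib_range Library-size multipliers drawn log-uniform in this range.
#' @param x_lnc_shift Planted log2 shift applied to X-chromosome lncRNAs in
#'   the mutant, in the sexes listed in `x_shift_sexes` (default: males,
#'   where X dosage effects concentrate).
#' @param x_shift_sexes Sexes receiving `x_lnc_shift`.
#' @param class_shifts Named log2 shifts applied to autosomal lncRNAs of
#'   each class in the mutant (both sexes).
#' @param de_pattern_counts Named counts of mRNAs planted as differentially
#'   expressed under each sex pattern (`both_up`, `both_down`,
#'   `F_up_M_down`, `F_down_M_up`, `F_up`, `F_down`, `M_up`, `M_down`).
#' @param de_lfc Magnitude (log2) of planted DE fold changes.
#' @param n_coexpr_pairs Number of lncRNA-mRNA pairs sharing a latent factor.
#' @param coexpr_latent_sd SD (log2) of the shared per-sample latent factor.
#' @param pair_base_mean,pair_dispersion Baseline mean and dispersion of
#'   pair-member transcripts (high mean / low dispersion so the latent
#'   factor dominates sampling noise).
#' @param te_up_families,te_down_families Families planted up-/down-regulated
#'   in the mutant (log2 magnitude `te_de_lfc`), with baseline mean
#'   `te_de_base_mean` so they clear the expression filter.
#' @param te_de_lfc,te_de_base_mean See above.
#' @param embryo List of embryo-measurement parameters: `n_per_group`
#'   embryos per (genotype, stage); probe-channel means per stage for WT and
#'   mutant (`probe_mean_wt`, `probe_mean_mut`), `probe_sd`; DAPI-channel
#'   `dapi_mean`, `dapi_sd`. Stage groups are fixed to St1-5, St6-11,
#'   St12-17.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = c("2L", "2R", "3L", "3R", "4", "X"),
                       chrom_length = 3e6,
                       n_genes_per_chrom = 80,
                       lnc_class_counts = c(lincRNA = 584, intronic = 254,
                                            sense = 95, antisense = 67),
                       te_families = c("copia", "297", "flea", "Burdock",
                                       "Tirant", "HMS-Beagle", "Rt1b",
                                       "jockey"),
                       n_te_per_family = 15,
                       decoy_counts = c(single_exon = 5, short = 5,
                                        coding = 5, homology = 5),
                       n_rep = 3,
                       base_mean = 150,
                       base_mean_sdlog = 1,
                       dispersion = 0.05,
                       lib_range = c(0.7, 1.4),
                       x_lnc_shift = 1.0,
                       x_shift_sexes = "M",
                       class_shifts = c(lincRNA = 0.4, intronic = -0.2,
                                        sense = 0, antisense = 0),
                       de_pattern_counts = c(both_up = 15, both_down = 15,
                                             F_up_M_down = 5, F_down_M_up = 5,
                                             F_up = 10, F_down = 10,
                                             M_up = 10, M_down = 10),
                       de_lfc = 2,
                       n_coexpr_pairs = 20,
                       coexpr_latent_sd = 0.9,
                       pair_base_mean = 2000,
                       pair_dispersion = 0.005,
                       te_up_families = c("copia", "297", "flea"),
                       te_down_families = c("HMS-Beagle", "Rt1b", "jockey"),
                       te_de_lfc = 1.5,
                       te_de_base_mean = 1500,
                       embryo = list(n_per_group = 8,
                                     probe_mean_wt = c(100, 100, 100),
                                     probe_mean_mut = c(95, 75, 55),
                                     probe_sd = 10,
                                     dapi_mean = 50,
                                     dapi_sd = 5)) {
  cfg <- as.list(environment())
  stopifnot(length(seed) == 1, is.finite(seed))
  cfg$seed <- as.integer(seed)
  if (cfg$base_mean <= 0 || cfg$pair_base_mean <= 0 ||
      cfg$te_de_base_mean <= 0) {
    stop("all baseline means must be > 0", call. = FALSE)
  }
  if (cfg$dispersion < 0 || cfg$pair_dispersion < 0) {
    stop("dispersion must be >= 0", call. = FALSE)
  }
  need_cls <- c("lincRNA", "intronic", "sense", "antisense")
  if (!all(need_cls %in% names(cfg$lnc_class_counts))) {
    stop("lnc_class_counts must name all of: ",
         paste(need_cls, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$lib_range <= 0) || cfg$lib_range[1] > cfg$lib_range[2]) {
    stop("lib_range must be positive and ordered", call. = FALSE)
  }
  em <- cfg$embryo
  if (em$dapi_mean <= 0) stop("DAPI mean must be > 0", call. = FALSE)
  if (em$probe_sd < 0 || em$dapi_sd < 0) {
    stop("SD must be >= 0", call. = FALSE)
  }
  if (any(em$probe_mean_wt < 0) || any(em$probe_mean_mut < 0)) {
    stop("probe means must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.STAGES <- c("St1-5", "St6-11", "St12-17")

# run `expr` under a seed derived from the config seed and a small stream
# offset, restoring the caller's RNG state afterwards
.with_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% 2100000000L + offset)
  expr
}

# exon-interval layout for one free-standing transcript, relative to start 1
.tx_layout <- function(n_ex, exon_lens, intron_lens) {
  starts <- integer(n_ex)
  ends <- integer(n_ex)
  pos <- 1L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + (if (i < n_ex) intron_lens[i] else 0L) + 1L
  }
  list(starts = starts, ends = ends, span = ends[n_ex])
}

#' Generate a synthetic genome annotation with truth labels
#'
#' Places protein-coding genes along each chromosome, then plants lncRNAs so
#' each positional class holds by construction: lincRNAs in intergenic gaps
#' (zero overlap with any gene span); intronic lncRNAs fully inside a host
#' intron on the host strand; sense lncRNAs with a same-strand exon-exon
#' overlap; antisense lncRNAs inside a host gene on the opposite strand.
#' TE instances and discovery decoys (single-exon, sub-200-nt, coding-ORF
#' and homology-hit transcripts) are planted alongside.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (a [genome_annotation()]) and `truth`
#'   (a tibble: `transcript_id`, `role` — one of the four lncRNA classes,
#'   `mRNA`, `TE`, or a `decoy_*` label — plus `chromosome` and, for TEs,
#'   `family`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, 0L, .generate_annotation_impl(config))
}

.generate_annotation_impl <- function(config) {
  chroms <- config$chromosomes
  n_chrom <- length(chroms)

  cls_counts <- config$lnc_class_counts
  te_n <- length(config$te_families) * config$n_te_per_family
  te_fam <- rep(config$te_families, each = config$n_te_per_family)
  dec <- config$decoy_counts

  # chromosome assignment, round-robin so every arm carries every class
  assign_rr <- function(n) rep(chroms, length.out = n)
  linc_chrom <- assign_rr(cls_counts[["lincRNA"]])
  te_chrom <- assign_rr(te_n)
  dec_types <- rep(names(dec), times = dec)
  dec_chrom <- assign_rr(length(dec_types))

  genes <- list(); transcripts <- list(); exons <- list(); truth <- list()
  gene_registry <- list()  # per chromosome: placed gene structures

  free_items <- function(chrom) {
    # free-standing items on this chromosome: genes, lincRNAs, TEs, decoys
    items <- c(
      replicate(config$n_genes_per_chrom, list(kind = "gene"),
                simplify = FALSE),
      lapply(which(linc_chrom == chrom),
             function(k) list(kind = "lincRNA", idx = k)),
      lapply(which(te_chrom == chrom),
             function(k) list(kind = "TE", idx = k)),
      lapply(which(dec_chrom == chrom),
             function(k) list(kind = dec_types[k], idx = k))
    )
    items[sample.int(length(items))]
  }

  for (chrom in chroms) {
    items <- free_items(chrom)
    cursor <- 1000L
    g_i <- 0L
    placed_genes <- list()
    for (it in items) {
      if (it$kind == "gene") {
        g_i <- g_i + 1L
        n_ex <- sample(2:5, 1)
        lay <- .tx_layout(n_ex, sample(200:600, n_ex, replace = TRUE),
                          sample(800:2000, max(n_ex - 1, 1), replace = TRUE))
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("g_%s_%03d", chrom, g_i)
        tid <- sprintf("mRNA_%s_%03d", chrom, g_i)
        genes[[length(genes) + 1L]] <- tibble::tibble(
          gene_id = gid, chromosome = chrom, strand = strand,
          start = cursor, end = cursor + lay$span - 1L,
          biotype = "protein_coding")
        transcripts[[length(transcripts) + 1L]] <- tibble::tibble(
          transcript_id = tid, gene_id = gid, chromosome = chrom,
          strand = strand, biotype = "protein_coding")
        exons[[length(exons) + 1L]] <- tibble::tibble(
          transcript_id = tid, start = cursor + lay$starts - 1L,
          end = cursor + lay$ends - 1L)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          transcript_id = tid, role = "mRNA", chromosome = chrom,
          family = NA_character_)
        placed_genes[[g_i]] <- list(
          gene_id = gid, strand = strand, start = cursor,
          exon_starts = cursor + lay$starts - 1L,
          exon_ends = cursor + lay$ends - 1L)
        cursor <- cursor + lay$span - 1L + sample(300:900, 1)
      } else {
        spec <- switch(
          it$kind,
          lincRNA = {
            n_ex <- sample(2:3, 1)
            list(id = sprintf("lnc_lincRNA_%04d", it$idx), role = "lincRNA",
                 biotype = "lncRNA", n_ex = n_ex,
                 ex = sample(100:400, n_ex, replace = TRUE),
                 intr = sample(100:500, max(n_ex - 1, 1), replace = TRUE))
          },
          TE = list(id = sprintf("te_%s_%03d", gsub("[^A-Za-z0-9]", "",
                                                    te_fam[it$idx]), it$idx),
                    role = "TE", biotype = "TE", n_ex = 1L,
                    ex = sample(400:4000, 1), intr = integer()),
          single_exon = list(id = sprintf("decoy_single_exon_%02d", it$idx),
                             role = "decoy_single_exon", biotype = "other",
                             n_ex = 1L, ex = sample(500:1000, 1),
                             intr = integer()),
          short = list(id = sprintf("decoy_short_%02d", it$idx),
                       role = "decoy_short", biotype = "other", n_ex = 2L,
                       ex = c(sample(60:99, 1), sample(60:99, 1)),
                       intr = sample(100:300, 1)),
          coding = {
            n_ex <- sample(2:3, 1)
            # long enough to host a >=100-codon open reading frame
            list(id = sprintf("decoy_coding_%02d", it$idx),
                 role = "decoy_coding", biotype = "other", n_ex = n_ex,
                 ex = sample(300:500, n_ex, replace = TRUE),
                 intr = sample(100:500, max(n_ex - 1, 1), replace = TRUE))
          },
          homology = {
            n_ex <- sample(2:3, 1)
            list(id = sprintf("decoy_homology_%02d", it$idx),
                 role = "decoy_homology", biotype = "other", n_ex = n_ex,
                 ex = sample(100:400, n_ex, replace = TRUE),
                 intr = sample(100:500, max(n_ex - 1, 1), replace = TRUE))
          }
        )
        lay <- .tx_layout(spec$n_ex, spec$ex, spec$intr)
        strand <- sample(c("+", "-"), 1)
        transcripts[[length(transcripts) + 1L]] <- tibble::tibble(
          transcript_id = spec$id, gene_id = NA_character_,
          chromosome = chrom, strand = strand, biotype = spec$biotype)
        exons[[length(exons) + 1L]] <- tibble::tibble(
          transcript_id = spec$id, start = cursor + lay$starts - 1L,
          end = cursor + lay$ends - 1L)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          transcript_id = spec$id, role = spec$role, chromosome = chrom,
          family = if (spec$role == "TE") te_fam[it$idx] else NA_character_)
        cursor <- cursor + lay$span - 1L + sample(200:600, 1)
      }
    }
    if (cursor > config$chrom_length) {
      stop(sprintf(
        "chromosome %s too short (%d nt needed, %d available); increase chrom_length or reduce features",
        chrom, cursor, as.integer(config$chrom_length)), call. = FALSE)
    }
    gene_registry[[chrom]] <- placed_genes
  }

  # gene-attached lncRNA classes: intronic, sense, antisense
  attach_one <- function(class, k, chrom) {
    hosts <- gene_registry[[chrom]]
    hosts <- hosts[vapply(hosts, function(g) length(g$exon_starts) >= 2,
                          logical(1))]
    if (length(hosts) == 0) {
      stop("no multi-exon host gene on chromosome ", chrom, call. = FALSE)
    }
    host <- hosts[[(k - 1L) %% length(hosts) + 1L]]
    intron1 <- c(host$exon_ends[1] + 1L, host$exon_starts[2] - 1L)
    id <- sprintf("lnc_%s_%04d", class, k)
    if (class == "intronic") {
      # fully inside intron 1, host strand: no exonic overlap by construction
      lens <- sample(100:150, 2, replace = TRUE)
      gap <- sample(60:120, 1)
      s1 <- intron1[1] + 10L
      starts <- c(s1, s1 + lens[1] + gap)
      ends <- starts + lens - 1L
      stopifnot(ends[2] <= intron1[2] - 10L)
      strand <- host$strand
    } else if (class == "sense") {
      # first exon inside the host's first exon (same strand), second in
      # intron 1: guarantees an exon-to-exon same-strand overlap; exon
      # lengths keep the transcript at or above the 200 nt floor
      len1 <- sample(100:150, 1)
      len2 <- sample(100:150, 1)
      s1 <- host$exon_starts[1] + 10L
      s2 <- intron1[1] + 20L
      starts <- c(s1, s2)
      ends <- c(s1 + len1 - 1L, s2 + len2 - 1L)
      stopifnot(ends[1] <= host$exon_ends[1], ends[2] <= intron1[2])
      strand <- host$strand
    } else { # antisense: inside the host span on the opposite strand
      lens <- sample(100:150, 2, replace = TRUE)
      gap <- sample(60:120, 1)
      s1 <- intron1[1] + 10L
      starts <- c(s1, s1 + lens[1] + gap)
      ends <- starts + lens - 1L
      stopifnot(ends[2] <= intron1[2] - 10L)
      strand <- if (host$strand == "+") "-" else "+"
    }
    list(
      tx = tibble::tibble(transcript_id = id, gene_id = NA_character_,
                          chromosome = chrom, strand = strand,
                          biotype = "lncRNA"),
      ex = tibble::tibble(transcript_id = id, start = starts, end = ends),
      truth = tibble::tibble(transcript_id = id, role = class,
                             chromosome = chrom, family = NA_character_)
    )
  }

  for (class in c("intronic", "sense", "antisense")) {
    n <- cls_counts[[class]]
    if (n == 0) next
    chrom_of <- assign_rr(n)
    for (k in seq_len(n)) {
      res <- attach_one(class, k, chrom_of[k])
      transcripts[[length(transcripts) + 1L]] <- res$tx
      exons[[length(exons) + 1L]] <- res$ex
      truth[[length(truth) + 1L]] <- res$truth
    }
  }

  # lincRNAs share free placement above; biotype for lincRNA rows is set there
  ann <- genome_annotation(
    genes = dplyr::bind_rows(genes),
    transcripts = dplyr::bind_rows(transcripts),
    exons = dplyr::bind_rows(exons)
  )
  list(annotation = ann, truth = dplyr::bind_rows(truth))
}

# per-transcript, per-sex planted log2 effects (applied in the mutant)
.planted_effects <- function(truth, config) {
  lnc_classes <- c("lincRNA", "intronic", "sense", "antisense")
  eff <- truth |>
    dplyr::mutate(
      is_lnc = .data$role %in% lnc_classes,
      on_x = .data$chromosome == "X",
      eff_F = 0, eff_M = 0
    )
  for (sx in c("F", "M")) {
    col <- paste0("eff_", sx)
    x_hit <- eff$is_lnc & eff$on_x & sx %in% config$x_shift_sexes
    eff[[col]][x_hit] <- config$x_lnc_shift
    auto_lnc <- eff$is_lnc & !eff$on_x
    eff[[col]][auto_lnc] <- unname(
      config$class_shifts[eff$role[auto_lnc]])
  }
  # planted DE mRNAs
  mrna_ids <- eff$transcript_id[eff$role == "mRNA"]
  pat <- config$de_pattern_counts
  pat <- pat[pat > 0]
  n_de <- sum(pat)
  de_tbl <- tibble::tibble(transcript_id = character(),
                           pattern = character(),
                           lfc_F = double(), lfc_M = double())
  if (n_de > 0) {
    if (n_de > length(mrna_ids)) {
      stop("more planted DE mRNAs requested than mRNAs generated",
           call. = FALSE)
    }
    chosen <- sample(mrna_ids, n_de)
    patterns <- rep(names(pat), times = pat)
    l <- config$de_lfc
    lf <- c(both_up = l, both_down = -l, F_up_M_down = l, F_down_M_up = -l,
            F_up = l, F_down = -l, M_up = 0, M_down = 0)
    lm <- c(both_up = l, both_down = -l, F_up_M_down = -l, F_down_M_up = l,
            F_up = 0, F_down = 0, M_up = l, M_down = -l)
    de_tbl <- tibble::tibble(transcript_id = chosen, pattern = patterns,
                             lfc_F = unname(lf[patterns]),
                             lfc_M = unname(lm[patterns]))
    idx <- match(de_tbl$transcript_id, eff$transcript_id)
    eff$eff_F[idx] <- de_tbl$lfc_F
    eff$eff_M[idx] <- de_tbl$lfc_M
  }
  # TE families with planted direction
  te_dir <- ifelse(truth$family %in% config$te_up_families, 1,
                   ifelse(truth$family %in% config$te_down_families, -1, 0))
  te_dir[is.na(truth$family)] <- 0
  eff$eff_F <- eff$eff_F + te_dir * config$te_de_lfc
  eff$eff_M <- eff$eff_M + te_dir * config$te_de_lfc
  list(effects = dplyr::select(eff, "transcript_id", "role", "chromosome",
                               "family", "eff_F", "eff_M"),
       de = de_tbl)
}

.nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu,
                                                 size = 1 / dispersion)
}

#' Generate a synthetic count matrix with planted effects
#'
#' Draws negative-binomial counts for every transcript of a generated
#' annotation across the full design (WT/ISWI x F/M x `n_rep` replicates).
#' Planted effects — the X-lncRNA dosage shift, autosomal per-class lncRNA
#' shifts, DE mRNA fold changes, TE family shifts and latent-factor
#' co-expressed pairs — are applied multiplicatively to the mutant group
#' mean. Per-sample library-size multipliers (log-uniform in
#' `config$lib_range`) scale every transcript of a sample and are recorded
#' in the truth set for recovery checks.
#'
#' @param annotation A [genome_annotation()] from [generate_annotation()].
#' @param config The [sim_config()] used to generate it.
#' @param truth The truth tibble returned by [generate_annotation()].
#' @return A list: `counts` (a [count_matrix()] over all 4 x `n_rep`
#'   samples), and `truth` — a list with `effects` (per-transcript per-sex
#'   planted log2 shifts), `de` (planted DE mRNAs with per-sex fold
#'   changes), `pairs` (planted co-expressed lncRNA-mRNA pairs),
#'   `lib_factors`, and `base_mean`.
#' @export
generate_counts <- function(annotation, config, truth) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  .with_seed(config$seed, 1L, .generate_counts_impl(annotation, config, truth))
}

.generate_counts_impl <- function(annotation, config, truth) {
  tx <- annotation$transcripts
  truth <- truth[match(tx$transcript_id, truth$transcript_id), ]
  pl <- .planted_effects(truth, config)
  eff <- pl$effects

  n_tx <- nrow(tx)
  samples <- tidyr::expand_grid(
    genotype = c("WT", "ISWI"), sex = c("F", "M"),
    replicate = seq_len(config$n_rep)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_%d", .data$genotype, .data$sex,
                                      .data$replicate)) |>
    dplyr::select("sample_id", "genotype", "sex", "replicate")
  n_s <- nrow(samples)

  base_mu <- stats::rlnorm(n_tx, meanlog = log(config$base_mean),
                           sdlog = config$base_mean_sdlog)
  # TE instances in planted-DE families get the high-expression baseline
  te_de <- !is.na(truth$family) &
    truth$family %in% c(config$te_up_families, config$te_down_families)
  base_mu[te_de] <- stats::rlnorm(sum(te_de),
                                  meanlog = log(config$te_de_base_mean),
                                  sdlog = 0.3)

  # latent-factor co-expressed pairs among lincRNAs and non-DE mRNAs
  lnc_ids <- truth$transcript_id[truth$role == "lincRNA"]
  mrna_ids <- setdiff(truth$transcript_id[truth$role == "mRNA"],
                      pl$de$transcript_id)
  n_pairs <- min(config$n_coexpr_pairs, length(lnc_ids), length(mrna_ids))
  pairs <- tibble::tibble(lncRNA_id = character(), mRNA_id = character())
  latent <- matrix(0, n_tx, n_s)
  disp <- rep(config$dispersion, n_tx)
  if (n_pairs > 0) {
    pairs <- tibble::tibble(lncRNA_id = sample(lnc_ids, n_pairs),
                            mRNA_id = sample(mrna_ids, n_pairs))
    z <- matrix(stats::rnorm(n_pairs * n_s, 0, config$coexpr_latent_sd),
                n_pairs, n_s)
    i_lnc <- match(pairs$lncRNA_id, tx$transcript_id)
    i_mrna <- match(pairs$mRNA_id, tx$transcript_id)
    latent[i_lnc, ] <- z
    latent[i_mrna, ] <- z
    base_mu[c(i_lnc, i_mrna)] <- config$pair_base_mean
    disp[c(i_lnc, i_mrna)] <- config$pair_dispersion
    # pair members carry no other planted effect: the latent factor is the
    # signal being recovered
    eff$eff_F[c(i_lnc, i_mrna)] <- 0
    eff$eff_M[c(i_lnc, i_mrna)] <- 0
  }

  lib <- exp(stats::runif(n_s, log(config$lib_range[1]),
                          log(config$lib_range[2])))
  is_mut <- samples$genotype == "ISWI"
  sex_eff <- cbind(F = eff$eff_F, M = eff$eff_M)

  mu <- matrix(0, n_tx, n_s)
  for (s in seq_len(n_s)) {
    e <- if (is_mut[s]) sex_eff[, samples$sex[s]] else 0
    mu[, s] <- base_mu * lib[s] * 2^(e + latent[, s])
  }
  counts <- matrix(0L, n_tx, n_s,
                   dimnames = list(tx$transcript_id, samples$sample_id))
  # per-transcript dispersion (pair members differ from the bulk)
  size <- ifelse(disp == 0, Inf, 1 / pmax(disp, 1e-12))
  fin <- is.finite(size)
  for (s in seq_len(n_s)) {
    col <- numeric(n_tx)
    if (any(fin)) {
      col[fin] <- stats::rnbinom(sum(fin), mu = mu[fin, s],
                                 size = size[fin])
    }
    if (any(!fin)) col[!fin] <- stats::rpois(sum(!fin), mu[!fin, s])
    counts[, s] <- col
  }

  list(
    counts = count_matrix(counts, samples),
    truth = list(
      effects = eff,
      de = pl$de,
      pairs = pairs,
      lib_factors = tibble::tibble(sample_id = samples$sample_id,
                                   factor = lib),
      base_mean = tibble::tibble(transcript_id = tx$transcript_id,
                                 base_mu = base_mu)
    )
  )
}

#' Generate synthetic transcript sequences
#'
#' Returns one mature (spliced, forward-strand) sequence per transcript.
#' Transcripts listed in `coding_ids` receive a planted open reading frame
#' of at least `orf_codons` codons; all others are built stop-dense (a
#' stop-codon cassette covering all three frames every ~45 nt) so their
#' longest ORF stays short and the coding verdict is unambiguous.
#'
#' @param annotation A [genome_annotation()].
#' @param config A [sim_config()] (supplies the seed).
#' @param coding_ids Transcript ids to receive a planted ORF.
#' @param orf_codons Length of the planted ORF in codons.
#' @return Named character vector of sequences over ACGT.
#' @export
generate_sequences <- function(annotation, config, coding_ids = character(),
                               orf_codons = 150) {
  stopifnot(inherits(annotation, "genome_annotation"))
  .with_seed(config$seed, 3L, {
    tx <- annotation$transcripts
    out <- character(nrow(tx))
    names(out) <- tx$transcript_id
    sense_codons <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1, paste0, collapse = ""),
      c("TAA", "TAG", "TGA"))
    cassette <- "TAATTAATTAA"  # stop codons in all three frames
    for (i in seq_len(nrow(tx))) {
      len <- tx$length[i]
      if (tx$transcript_id[i] %in% coding_ids) {
        orf <- paste0("ATG",
                      paste(sample(sense_codons, orf_codons - 2,
                                   replace = TRUE), collapse = ""),
                      "TAA")
        pad_n <- max(len - nchar(orf), 0)
        lead <- max(min(10L, pad_n), 0)
        pad <- paste(sample(c("A", "C", "T"), pad_n, replace = TRUE),
                     collapse = "")
        seq <- paste0(substr(pad, 1, lead), orf,
                      substr(pad, lead + 1, pad_n))
        out[i] <- substr(seq, 1, max(len, nchar(orf)))
      } else {
        blocks <- ceiling(len / (34 + nchar(cassette)))
        seq <- paste(vapply(seq_len(blocks), function(b) {
          paste0(paste(sample(c("A", "C", "G", "T"), 34, replace = TRUE),
                       collapse = ""), cassette)
        }, character(1)), collapse = "")
        out[i] <- substr(seq, 1, len)
      }
    }
    out
  })
}

#' Assemble the full discovery fixture
#'
#' Produces everything [run_discovery()] consumes, with known truth: the
#' reference annotation (genes, known lncRNAs, TEs), the assembled candidate
#' set (novel lncRNAs of all four classes plus the planted decoys, with
#' `gene_id` and biotype stripped as in a transcript-assembler output),
#' mature sequences, and a homology hit table in which the planted homology
#' decoys carry significant hits (E = 1e-6) and a few valid transcripts
#' carry benign hits (E = 1e-3) that must survive the strict E < 1e-5 rule.
#'
#' @param config A [sim_config()].
#' @return A list: `reference` and `assembled` annotations, `sequences`,
#'   `hits`, `annotation` (the full generated annotation), and `truth` with
#'   `planted_lnc` (ids that must survive discovery) and the full role
#'   table.
#' @export
simulate_discovery_input <- function(config) {
  gen <- generate_annotation(config)
  ann <- gen$annotation
  truth <- gen$truth

  lnc_classes <- c("lincRNA", "intronic", "sense", "antisense")
  cand_roles <- c(lnc_classes, paste0("decoy_", names(config$decoy_counts)))
  cand_ids <- truth$transcript_id[truth$role %in% cand_roles]

  tx <- ann$transcripts
  cand_tx <- tx[tx$transcript_id %in% cand_ids, ] |>
    dplyr::mutate(gene_id = NA_character_, biotype = "other") |>
    dplyr::select("transcript_id", "gene_id", "chromosome", "strand",
                  "biotype")
  assembled <- genome_annotation(
    genes = ann$genes[0, ],
    transcripts = cand_tx,
    exons = ann$exons[ann$exons$transcript_id %in% cand_ids, ]
  )
  ref_ids <- setdiff(tx$transcript_id, cand_ids)
  reference <- genome_annotation(
    genes = ann$genes,
    transcripts = dplyr::select(tx[tx$transcript_id %in% ref_ids, ],
                                "transcript_id", "gene_id", "chromosome",
                                "strand", "biotype"),
    exons = ann$exons[ann$exons$transcript_id %in% ref_ids, ]
  )

  coding_ids <- truth$transcript_id[truth$role == "decoy_coding"]
  seqs <- generate_sequences(assembled, config, coding_ids = coding_ids)

  hom_ids <- truth$transcript_id[truth$role == "decoy_homology"]
  planted_lnc <- truth$transcript_id[truth$role %in% lnc_classes]
  benign <- utils::head(planted_lnc, 3)
  hits <- tibble::tibble(
    transcript_id = c(hom_ids, benign),
    e_value = c(rep(1e-6, length(hom_ids)), rep(1e-3, length(benign))),
    source = "pfam"
  )

  list(reference = reference, assembled = assembled, sequences = seqs,
       hits = hits, annotation = ann,
       truth = list(planted_lnc = planted_lnc, roles = truth))
}

#' Generate a per-sex count matrix with planted fold changes
#'
#' A matrix-level generator for differential-expression calibration: one
#' sex, WT and mutant groups with `n_rep` replicates each, negative-binomial
#' counts at a common baseline mean, library-size multipliers log-uniform in
#' `lib_range`, and a planted per-transcript log2 fold change applied
#' multiplicatively in the mutant.
#'
#' @param n_transcripts Number of transcripts.
#' @param lfc Planted log2 fold changes: scalar recycled or length
#'   `n_transcripts` (0 = null).
#' @param base_mean Baseline mean counts (scalar or per-transcript).
#' @param dispersion NB dispersion.
#' @param n_rep Replicates per group.
#' @param lib_range Library-size multiplier range (log-uniform).
#' @param sex Sex label written into the sample sheet.
#' @param seed Integer seed.
#' @return A list: `counts` (a [count_matrix()]), `truth` (tibble with
#'   `transcript_id`, `lfc`), and `lib_factors` (the drawn library-size
#'   multipliers, for recovery checks).
#' @export
simulate_de_counts <- function(n_transcripts, lfc = 0, base_mean = 100,
                               dispersion = 0.05, n_rep = 3,
                               lib_range = c(0.7, 1.4), sex = "F",
                               seed = 1L) {
  stopifnot(n_transcripts >= 1, all(base_mean > 0), dispersion >= 0)
  .with_seed(as.integer(seed), 5L, {
    lfc <- rep_len(lfc, n_transcripts)
    mu0 <- rep_len(base_mean, n_transcripts)
    samples <- tibble::tibble(
      sample_id = c(sprintf("WT_%s_%d", sex, seq_len(n_rep)),
                    sprintf("ISWI_%s_%d", sex, seq_len(n_rep))),
      genotype = rep(c("WT", "ISWI"), each = n_rep),
      sex = sex, replicate = rep(seq_len(n_rep), 2))
    lib <- exp(stats::runif(2 * n_rep, log(lib_range[1]), log(lib_range[2])))
    counts <- matrix(
      0L, n_transcripts, 2 * n_rep,
      dimnames = list(sprintf("tx_%05d", seq_len(n_transcripts)),
                      samples$sample_id))
    for (s in seq_len(2 * n_rep)) {
      e <- if (samples$genotype[s] == "ISWI") lfc else 0
      counts[, s] <- .nb_draw(n_transcripts, mu0 * lib[s] * 2^e, dispersion)
    }
    list(counts = count_matrix(counts, samples),
         truth = tibble::tibble(transcript_id = rownames(counts), lfc = lfc),
         lib_factors = tibble::tibble(sample_id = samples$sample_id,
                                      factor = lib))
  })
}

#' Generate counts with planted co-expressed lncRNA-mRNA pairs
#'
#' `n_pairs` lncRNA-mRNA pairs share a per-sample latent factor (log2 SD
#' `latent_sd`) on top of negative-binomial noise, among `n_decoy`
#' independent decoys (half labelled lncRNA, half mRNA), across the full
#' 4-group x `n_rep` design.
#'
#' @param n_pairs Planted pairs.
#' @param n_decoy Independent decoy transcripts.
#' @param latent_sd SD of the shared latent factor (log2).
#' @param pair_base_mean,pair_dispersion NB parameters for pair members.
#' @param decoy_base_mean,decoy_dispersion NB parameters for decoys.
#' @param n_rep Replicates per (genotype, sex) group.
#' @param lib_range Library-size multiplier range.
#' @param seed Integer seed.
#' @return A list: `counts` (a [count_matrix()]), `lnc_ids`, `mrna_ids`,
#'   and `truth` (tibble of planted `lncRNA_id`, `mRNA_id`).
#' @export
simulate_coexpression_counts <- function(n_pairs = 20, n_decoy = 200,
                                         latent_sd = 0.9,
                                         pair_base_mean = 2000,
                                         pair_dispersion = 0.005,
                                         decoy_base_mean = 300,
                                         decoy_dispersion = 0.05,
                                         n_rep = 3,
                                         lib_range = c(0.7, 1.4),
                                         seed = 1L) {
  stopifnot(n_pairs >= 1, n_decoy >= 0)
  .with_seed(as.integer(seed), 7L, {
    samples <- tidyr::expand_grid(
      genotype = c("WT", "ISWI"), sex = c("F", "M"),
      replicate = seq_len(n_rep)) |>
      dplyr::mutate(sample_id = sprintf("%s_%s_%d", .data$genotype,
                                        .data$sex, .data$replicate)) |>
      dplyr::select("sample_id", "genotype", "sex", "replicate")
    n_s <- nrow(samples)
    n_half <- floor(n_decoy / 2)
    lnc_ids <- c(sprintf("lnc_pair_%03d", seq_len(n_pairs)),
                 sprintf("lnc_decoy_%03d", seq_len(n_half)))
    mrna_ids <- c(sprintf("mRNA_pair_%03d", seq_len(n_pairs)),
                  sprintf("mRNA_decoy_%03d", seq_len(n_decoy - n_half)))
    ids <- c(lnc_ids, mrna_ids)
    n_tx <- length(ids)
    is_pair <- grepl("_pair_", ids)
    mu0 <- ifelse(is_pair, pair_base_mean, decoy_base_mean)
    disp <- ifelse(is_pair, pair_dispersion, decoy_dispersion)

    z <- matrix(stats::rnorm(n_pairs * n_s, 0, latent_sd), n_pairs, n_s)
    latent <- matrix(0, n_tx, n_s)
    latent[match(sprintf("lnc_pair_%03d", seq_len(n_pairs)), ids), ] <- z
    latent[match(sprintf("mRNA_pair_%03d", seq_len(n_pairs)), ids), ] <- z

    lib <- exp(stats::runif(n_s, log(lib_range[1]), log(lib_range[2])))
    counts <- matrix(0L, n_tx, n_s, dimnames = list(ids, samples$sample_id))
    size <- ifelse(disp == 0, Inf, 1 / pmax(disp, 1e-12))
    fin <- is.finite(size)
    for (s in seq_len(n_s)) {
      mu <- mu0 * lib[s] * 2^latent[, s]
      col <- numeric(n_tx)
      if (any(fin)) {
        col[fin] <- stats::rnbinom(sum(fin), mu = mu[fin], size = size[fin])
      }
      if (any(!fin)) col[!fin] <- stats::rpois(sum(!fin), mu[!fin])
      counts[, s] <- col
    }
    list(counts = count_matrix(counts, samples),
         lnc_ids = lnc_ids, mrna_ids = mrna_ids,
         truth = tibble::tibble(
           lncRNA_id = sprintf("lnc_pair_%03d", seq_len(n_pairs)),
           mRNA_id = sprintf("mRNA_pair_%03d", seq_len(n_pairs))))
  })
}

#' Generate a synthetic embryo fluorescence-measurement table
#'
#' Draws per-embryo probe-channel and DAPI-channel intensities from normal
#' distributions per (genotype, stage group), truncated at a small positive
#' floor. Stage groups follow the standard embryonic binning St1-5, St6-11,
#' St12-17.
#'
#' @param config A [sim_config()]; the `embryo` element supplies group
#'   means, SDs and embryos per group.
#' @return Tibble: `embryo_id`, `genotype`, `stage`, `probe`, `dapi`.
#' @export
generate_embryo_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  em <- config$embryo
  .with_seed(config$seed, 9L, {
    grid <- tidyr::expand_grid(genotype = c("WT", "ISWI"),
                               stage = .STAGES,
                               k = seq_len(em$n_per_group))
    probe_mean <- ifelse(grid$genotype == "WT",
                         em$probe_mean_wt[match(grid$stage, .STAGES)],
                         em$probe_mean_mut[match(grid$stage, .STAGES)])
    n <- nrow(grid)
    tibble::tibble(
      embryo_id = sprintf("emb_%s_%s_%02d", grid$genotype,
                          gsub("[^A-Za-z0-9]", "", grid$stage), grid$k),
      genotype = grid$genotype,
      stage = grid$stage,
      probe = pmax(stats::rnorm(n, probe_mean, em$probe_sd), 0),
      dapi = pmax(stats::rnorm(n, em$dapi_mean, em$dapi_sd), 1e-6)
    )
  })
}
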