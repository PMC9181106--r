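# End-to-end orchestration on synthetic data: discovery -> classification ->
# normalization -> dosage tables -> DE -> concordance -> co-expression ->
# TE summaries -> FISH statistics, each stage's table written to the output
# directory together with a run manifest. Reruns with the same config are
# byte-identical.

#' Run the full analysis pipeline on simulated data
#'
#' Generates a complete synthetic study from `config`, runs every stage in
#' order, writes one deterministic TSV per stage plus a JSON manifest
#' (package version, seed, config, per-stage record counts) and returns the
#' in-memory results.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing.
#' @return Invisibly, a list with elements `discovery`, `classes`,
#'   `proportions`, `normalized`, `ratios` (per sex), `medians` (per sex),
#'   `histograms` (per sex), `de` (per sex), `concordance`, `edges`,
#'   `degrees`, `te`, `fish`, and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))

  # --- simulate ----------------------------------------------------------
  sim <- simulate_discovery_input(config)
  cnt <- generate_counts(sim$annotation, config, sim$truth$roles)
  embryos <- generate_embryo_table(config)

  # --- discovery ---------------------------------------------------------
  disc <- run_discovery(sim$assembled, sequences = sim$sequences,
                        hits = sim$hits, reference = sim$reference)

  # --- classification ----------------------------------------------------
  classes <- classify_lncrnas(disc$novel_lncRNA, sim$annotation)
  proportions <- class_proportions(classes)

  # --- normalization and dosage analysis ---------------------------------
  norm <- normalize_counts(cnt$counts)
  class_lut <- dplyr::bind_rows(
    classes,
    tibble::tibble(
      transcript_id = setdiff(rownames(norm$normalized),
                              classes$transcript_id)
    ) |>
      dplyr::mutate(class = {
        bt <- sim$annotation$transcripts$biotype[
          match(.data$transcript_id,
                sim$annotation$transcripts$transcript_id)]
        ifelse(bt == "protein_coding", "mRNA", bt)
      })
  )
  ratios <- lapply(c(F = "F", M = "M"), function(sx) {
    group_log2_ratios(norm, sex = sx, classes = class_lut,
                      annotation = sim$annotation)
  })
  medians <- lapply(ratios, median_by_stratum)
  histograms <- lapply(ratios, ratio_histogram)

  # --- differential expression and concordance ---------------------------
  de <- lapply(c(F = "F", M = "M"), function(sx) {
    de_test(cnt$counts, sex = sx)
  })
  conc <- concordance(de$F, de$M)

  # --- co-expression -----------------------------------------------------
  lnc_ids <- intersect(class_lut$transcript_id[
    class_lut$class %in% c("lincRNA", "intronic", "sense", "antisense",
                           "lncRNA")], rownames(norm$normalized))
  mrna_ids <- sim$annotation$transcripts$transcript_id[
    sim$annotation$transcripts$biotype == "protein_coding"]
  edges <- screen_pairs(norm$normalized[lnc_ids, , drop = FALSE],
                        norm$normalized[mrna_ids, , drop = FALSE])
  degrees <- node_degrees(edges)

  # --- TE family analysis ------------------------------------------------
  te_roles <- sim$truth$roles
  te_ids <- te_roles$transcript_id[te_roles$role == "TE"]
  fam_tbl <- tibble::tibble(
    transcript_id = te_ids,
    family = te_roles$family[match(te_ids, te_roles$transcript_id)],
    chromosome = te_roles$chromosome[match(te_ids, te_roles$transcript_id)]
  )
  de_te <- dplyr::bind_rows(de$F[de$F$transcript_id %in% te_ids, ],
                            de$M[de$M$transcript_id %in% te_ids, ]) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(call = if (any(.data$call != "ns")) {
      .data$call[.data$call != "ns"][1]
    } else "ns", .groups = "drop")
  passing <- filter_de_te(de_te, norm$base_mean)
  fam <- te_family_summary(passing, fam_tbl)
  te_ranked <- rank_te_families(fam$summary)

  # --- FISH quantification ----------------------------------------------
  fish <- compare_fish_groups(embryos)

  manifest <- list(
    package = "lncdosage",
    version = as.character(utils::packageVersion("lncdosage")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list(
      discovery = nrow(disc$audit),
      novel_lncRNA = length(disc$novel_lncRNA),
      novel_mRNA = length(disc$novel_mRNA),
      classified = nrow(classes),
      ratio_records_F = nrow(ratios$F),
      ratio_records_M = nrow(ratios$M),
      de_tested_F = nrow(de$F),
      de_tested_M = nrow(de$M),
      both_sex_de = nrow(conc$categories),
      edges = nrow(edges),
      te_passing = nrow(passing),
      fish_stages = nrow(fish)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(classes, file.path(out_dir, "lncRNA_classes.tsv"),
                "classes")
    for (sx in c("F", "M")) {
      write_table(ratios[[sx]],
                  file.path(out_dir, sprintf("ratios_%s.tsv", sx)),
                  "ratio_records")
      write_table(medians[[sx]],
                  file.path(out_dir, sprintf("medians_%s.tsv", sx)),
                  "medians")
      write_table(de[[sx]],
                  file.path(out_dir, sprintf("de_%s.tsv", sx)),
                  "de_results")
    }
    write_table(edges, file.path(out_dir, "coexpression_edges.tsv"),
                "edges")
    write_table(te_ranked$table,
                file.path(out_dir, "te_family_summary.tsv"),
                "te_family_summary")
    write_table(fish, file.path(out_dir, "fish_stats.tsv"), "fish_stats")
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(
    discovery = disc, classes = classes, proportions = proportions,
    normalized = norm, ratios = ratios, medians = medians,
    histograms = histograms, de = de, concordance = conc, edges = edges,
    degrees = degrees, te = te_ranked, fish = fish, manifest = manifest
  ))
}
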