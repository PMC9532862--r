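#' Pipeline configuration
#'
#' Bundles inputs and stage thresholds for [run_pipeline()]. Defaults are
#' the conventional decision rules: FC >= 2 with p < 0.05 (circRNA,
#' miRNA), FC >= 2 with FDR < 0.05 (mRNA), SCC < -0.7, PCC > 0.9, sponge
#' alpha 0.05, ORA FDR <= 0.05, top-k = 50.
#'
#' @param simulate A [simulation_config()], used when `input_dir` is NULL.
#' @param input_dir Directory holding a [write_fixture_bundle()]-style
#'   bundle to analyse instead of simulating.
#' @param comparison Two group labels, contrast is `comparison[2]` over
#'   `comparison[1]`.
#' @param scc_threshold,pcc_threshold Strict correlation cutoffs.
#' @param sponge_alpha Strict sponge-test level.
#' @param sponge_fdr Apply BH across sponge tests instead of raw p.
#' @param min_site_type Weakest qualifying seed-site class.
#' @param top_k Edges kept in the core sub-network.
#' @param ora_fdr ORA significance threshold (non-strict).
#' @param annotation Optional path to a term-feature TSV for ORA.
#' @param out_dir Output directory; NULL returns results without writing.
#' @return A `spng_pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            input_dir = NULL,
                            comparison = c("TN", "TL"),
                            scc_threshold = -0.7,
                            pcc_threshold = 0.9,
                            sponge_alpha = 0.05,
                            sponge_fdr = FALSE,
                            min_site_type = "7mer-A1",
                            top_k = 50,
                            ora_fdr = 0.05,
                            annotation = NULL,
                            out_dir = NULL) {
  if (length(comparison) != 2) abort("comparison must name two groups")
  if (scc_threshold >= 0 || scc_threshold < -1) abort("scc_threshold in [-1, 0)")
  if (pcc_threshold <= 0 || pcc_threshold > 1) abort("pcc_threshold in (0, 1]")
  if (sponge_alpha <= 0 || sponge_alpha > 1) abort("sponge_alpha in (0, 1]")
  if (top_k < 1) abort("top_k must be >= 1")
  structure(list(simulate = simulate, input_dir = input_dir,
                 comparison = comparison, scc_threshold = scc_threshold,
                 pcc_threshold = pcc_threshold, sponge_alpha = sponge_alpha,
                 sponge_fdr = sponge_fdr, min_site_type = min_site_type,
                 top_k = top_k, ora_fdr = ora_fdr, annotation = annotation,
                 out_dir = out_dir),
            class = "spng_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulate`
#' block holds [simulation_config()] fields.
#'
#' @param path YAML file.
#' @return A `spng_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  y$simulate <- do.call(simulation_config, sim_args)
  if (!is.null(y$comparison)) y$comparison <- as.character(y$comparison)
  do.call(pipeline_config, y)
}

#' Infer a ceRNA network from a three-layer dataset
#'
#' The in-memory analysis engine: normalizes each layer with its
#' conventional unit, calls differential expression for the comparison,
#' predicts seed-match targets of the DE miRNAs among the DE circRNAs
#' (circular scan) and DE mRNAs (linear scan), applies the Spearman
#' (< `scc_threshold`) and Pearson (> `pcc_threshold`) coexpression
#' filters on log2(normalized + 1) values over the comparison samples,
#' runs the shared-miRNA sponge test for every circRNA-mRNA candidate
#' (universe: miRNAs with at least one predicted target), assembles
#' triples and builds the network.
#'
#' @param counts Named list of raw-count matrices (circRNA, miRNA, mRNA).
#' @param design A [sample_design()] table.
#' @param sequences Named list of RNA sequence vectors (mirna, utr, circ).
#' @param lengths Named length vector covering miRNA and mRNA features.
#' @param comparison Two group labels.
#' @inheritParams pipeline_config
#' @return List: normalized, de (per layer), candidates (per target
#'   layer), edges (circ_mir, mir_mrna, circ_mrna), sponge, triples,
#'   network, top, summaries.
#' @export
infer_cerna <- function(counts, design, sequences, lengths,
                        comparison = c("TN", "TL"),
                        scc_threshold = -0.7, pcc_threshold = 0.9,
                        sponge_alpha = 0.05, sponge_fdr = FALSE,
                        min_site_type = "7mer-A1", top_k = 50) {
  design <- sample_design(design)
  normalized <- list(
    circRNA = rpm(counts$circRNA),
    miRNA = tpm(counts$miRNA, lengths),
    mRNA = fpkm(counts$mRNA, lengths))
  de <- purrr::imap(counts, ~ de_test(.x, design, comparison))

  de_ids <- purrr::map(de, ~ filter(.x, .data$call != "ns")$feature)
  mir_seqs <- sequences$mirna[intersect(names(sequences$mirna), de_ids$miRNA)]
  circ_seqs <- sequences$circ[intersect(names(sequences$circ), de_ids$circRNA)]
  utr_seqs <- sequences$utr[intersect(names(sequences$utr), de_ids$mRNA)]

  cand_circ <- predict_pairs(mir_seqs, circ_seqs, layer = "circRNA",
                             min_site_type = min_site_type)
  cand_mrna <- predict_pairs(mir_seqs, utr_seqs, layer = "mRNA",
                             min_site_type = min_site_type)

  samples <- design_samples(design, comparison)
  logs <- purrr::map(normalized, log_expression, samples = samples)

  edge_cm <- filter_negative_pairs(cand_circ, logs$miRNA, logs$circRNA,
                                   threshold = scc_threshold)
  edge_mg <- filter_negative_pairs(cand_mrna, logs$miRNA, logs$mRNA,
                                   threshold = scc_threshold)

  # circRNA-mRNA pairs sharing at least one predicted miRNA
  shared <- inner_join(
    distinct(cand_circ, .data$mirna, circ = .data$target),
    distinct(cand_mrna, .data$mirna, mrna = .data$target),
    by = "mirna", relationship = "many-to-many")
  cg_pairs <- distinct(shared, .data$circ, .data$mrna)
  edge_cg <- filter_positive_pairs(cg_pairs, logs$circRNA, logs$mRNA,
                                   threshold = pcc_threshold)

  universe <- union(unique(cand_circ$mirna), unique(cand_mrna$mirna))
  circ_sets <- split(cand_circ$mirna, cand_circ$target)
  mrna_sets <- split(cand_mrna$mirna, cand_mrna$target)
  sponge <- if (nrow(cg_pairs) > 0 && length(universe) > 0) {
    purrr::map2_dfr(cg_pairs$circ, cg_pairs$mrna, function(c, g) {
      res <- sponge_test(circ_sets[[c]] %||% character(),
                         mrna_sets[[g]] %||% character(),
                         universe, alpha = sponge_alpha)
      mutate(res, circ = c, mrna = g, .before = 1)
    })
  } else {
    tibble(circ = character(), mrna = character(), k = integer(),
           K = integer(), n = integer(), N = integer(), p = numeric(),
           passed = logical())
  }
  if (sponge_fdr && nrow(sponge) > 0) {
    sponge$p_adj <- bh_adjust(sponge$p)
    sponge$passed <- sponge$p_adj < sponge_alpha & sponge$k >= 1
  }

  triples <- assemble_triples(edge_cm, edge_mg, edge_cg, sponge)
  network <- build_network(triples)
  top <- top_edges(network, k = top_k)

  list(normalized = normalized, de = de,
       candidates = list(circRNA = cand_circ, mRNA = cand_mrna),
       edges = list(circ_mir = edge_cm, mir_mrna = edge_mg,
                    circ_mrna = edge_cg),
       sponge = sponge, triples = triples, network = network, top = top,
       summaries = list(
         de = purrr::imap_chr(de, ~ de_summary(.x)),
         network = network_summary(network),
         n_sponge_tests = nrow(sponge)),
       comparison = comparison)
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or reads) the dataset, runs [infer_cerna()], evaluates
#' recovery against ground truth when available, optionally runs ORA on
#' the differentially expressed mRNAs, and — when `out_dir` is set —
#' writes every table, the GraphML/SIF exports and a run manifest with
#' parameter echo and file checksums. Identical config and seed reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List: `data` (the dataset), `result` (from [infer_cerna()]),
#'   `recovery` (or NULL), `enrichment` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "spng_pipeline_config"))
    abort("config must come from pipeline_config()")
  data <- if (is.null(config$input_dir)) {
    simulate_dataset(config$simulate)
  } else {
    read_fixture_bundle(config$input_dir)
  }
  result <- infer_cerna(data$counts, data$design, data$sequences,
                        data$lengths, comparison = config$comparison,
                        scc_threshold = config$scc_threshold,
                        pcc_threshold = config$pcc_threshold,
                        sponge_alpha = config$sponge_alpha,
                        sponge_fdr = config$sponge_fdr,
                        min_site_type = config$min_site_type,
                        top_k = config$top_k)
  recovery <- if (!is.null(data$truth))
    evaluate_recovery(result$triples, data$truth) else NULL
  enrichment <- if (!is.null(config$annotation)) {
    ann <- read_annotation_tsv(config$annotation)
    de_mrna <- filter(result$de$mRNA, .data$call != "ns")$feature
    if (length(intersect(de_mrna, ann$universe)) > 0)
      ora(de_mrna, ann, fdr_threshold = config$ora_fdr) else NULL
  } else NULL

  manifest <- list(
    package = "spongenet",
    parameters = list(
      comparison = config$comparison,
      de_rules = list(circRNA = "|log2FC| >= 1 & p < 0.05",
                      miRNA = "|log2FC| >= 1 & p < 0.05",
                      mRNA = "|log2FC| >= 1 & FDR < 0.05"),
      scc_threshold = config$scc_threshold,
      pcc_threshold = config$pcc_threshold,
      sponge_alpha = config$sponge_alpha,
      sponge_fdr = config$sponge_fdr,
      min_site_type = config$min_site_type,
      top_k = config$top_k,
      ora_fdr = config$ora_fdr,
      seed = if (is.null(config$input_dir)) config$simulate$seed else NA),
    summaries = c(result$summaries,
                  list(recovery = recovery)))

  if (!is.null(config$out_dir)) {
    manifest$files <- write_pipeline_outputs(config$out_dir, data, result,
                                             recovery, enrichment)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(data = data, result = result, recovery = recovery,
       enrichment = enrichment, manifest = manifest)
}

write_pipeline_outputs <- function(out_dir, data, result, recovery,
                                   enrichment) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f <- function(name) file.path(out_dir, name)
  for (layer in names(result$de))
    readr::write_tsv(result$de[[layer]], f(sprintf("de_%s.tsv", layer)),
                     progress = FALSE)
  readr::write_tsv(bind_rows(result$candidates), f("candidate_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(bind_rows(result$edges), f("correlation_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$sponge, f("sponge_tests.tsv"), progress = FALSE)
  readr::write_tsv(result$triples, f("cerna_triples.tsv"), progress = FALSE)
  write_graphml(result$network, f("network.graphml"))
  write_sif(result$network, f("network.sif"))
  write_node_attributes(result$network, f("node_attributes.tsv"))
  write_sif(result$top, f("network_top.sif"))
  if (!is.null(recovery))
    readr::write_tsv(tibble::as_tibble(recovery), f("recovery.tsv"),
                     progress = FALSE)
  if (!is.null(enrichment))
    readr::write_tsv(enrichment, f("enrichment.tsv"), progress = FALSE)
  files <- list.files(out_dir, recursive = FALSE)
  files <- setdiff(files, "manifest.json")
  as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))), files))
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param path Bundle directory.
#' @return The dataset list ([simulate_dataset()] shape); `truth` is NULL
#'   when no ground-truth file is present.
#' @export
read_fixture_bundle <- function(path) {
  f <- function(name) file.path(path, name)
  counts <- list(
    circRNA = read_expr_tsv(f("counts_circRNA.tsv"), layer = "circRNA"),
    miRNA = read_expr_tsv(f("counts_miRNA.tsv"), layer = "miRNA"),
    mRNA = read_expr_tsv(f("counts_mRNA.tsv"), layer = "mRNA"))
  design <- sample_design(readr::read_tsv(f("design.tsv"),
                                          show_col_types = FALSE,
                                          progress = FALSE))
  truth <- if (file.exists(f("ground_truth.json")))
    read_ground_truth(f("ground_truth.json")) else NULL
  list(counts = counts, design = design,
       sequences = list(mirna = read_rna_fasta(f("mirna.fa")),
                        utr = read_rna_fasta(f("utr.fa")),
                        circ = read_rna_fasta(f("circ.fa"))),
       lengths = read_lengths_tsv(f("lengths.tsv")),
       truth = truth)
}
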