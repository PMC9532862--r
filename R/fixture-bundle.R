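#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_counts()] and
#' [simulate_sequences()] under one configuration.
#'
#' @param config A [simulation_config()].
#' @return List: counts, design, sequences (mirna/utr/circ), lengths,
#'   truth (planted_de, planted_triples, planted_pairs, planted_sites).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  sim <- simulate_counts(config)
  seqs <- simulate_sequences(config, sim)
  sim$truth$planted_sites <- seqs$sites
  list(counts = sim$counts, design = sim$design,
       sequences = seqs[c("mirna", "utr", "circ")],
       lengths = seqs$lengths, truth = sim$truth, config = config)
}

#' Write a simulated dataset to disk as plain-text files
#'
#' Emits the count TSVs, design TSV, length TSV, FASTA files, a
#' ground-truth JSON and a manifest JSON listing the md5 checksum of every
#' written file. Round-tripping the files reproduces the in-memory
#' objects; identical config + seed reproduces identical bytes.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param path Output directory (created if missing).
#' @return The manifest as a list (invisibly written to
#'   `manifest.json`).
#' @export
write_fixture_bundle <- function(dataset, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", path))
  }
  f <- function(name) file.path(path, name)
  write_expr_tsv(dataset$counts$circRNA, f("counts_circRNA.tsv"))
  write_expr_tsv(dataset$counts$miRNA, f("counts_miRNA.tsv"))
  write_expr_tsv(dataset$counts$mRNA, f("counts_mRNA.tsv"))
  readr::write_tsv(dataset$design[, c("sample", "breed", "oxygen", "replicate")],
                   f("design.tsv"), progress = FALSE)
  write_lengths_tsv(dataset$lengths, f("lengths.tsv"))
  write_rna_fasta(dataset$sequences$mirna, f("mirna.fa"))
  write_rna_fasta(dataset$sequences$utr, f("utr.fa"))
  write_rna_fasta(dataset$sequences$circ, f("circ.fa"))
  truth <- purrr::map(dataset$truth, ~ as.data.frame(.x))
  jsonlite::write_json(truth, f("ground_truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("counts_circRNA.tsv", "counts_miRNA.tsv", "counts_mRNA.tsv",
             "design.tsv", "lengths.tsv", "mirna.fa", "utr.fa", "circ.fa",
             "ground_truth.json")
  manifest <- list(
    package = "spongenet",
    seed = dataset$config$seed,
    config = unclass(dataset$config),
    files = as.list(tools::md5sum(file.path(path, files))
                    |> setNames(files))
  )
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a ground-truth JSON back into tibbles
#'
#' @param path Path to `ground_truth.json`.
#' @return List of tibbles (planted_de, planted_triples, planted_pairs,
#'   planted_sites).
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(raw, tibble::as_tibble)
}
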