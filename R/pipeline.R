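## Pipeline configuration and the end-to-end run over synthetic data.
## Defaults equal the stated analysis parameters: 20-nt anchors, >= 2
## junction reads, <= 100 kb span, tissue-specificity cutoff 0.9, DE calls
## at FDR < 0.05 with fold change > 2 or < 0.5. Every output table carries
## a provenance header (package version, seed, config hash).

#' Pipeline configuration
#'
#' Detection, expression, decoy and conservation parameters with the
#' analysis defaults, plus the synthetic-data scale used by [run_all()].
#'
#' @param seed integer seed for all stages.
#' @param anchor_length detection anchor length (nt).
#' @param min_reads minimum junction reads per reported circRNA.
#' @param max_dist maximum back-splice span (nt).
#' @param max_mismatch substitution tolerance for linear mapping.
#' @param tissue_index_cutoff tissue-specificity call threshold.
#' @param de_fdr,de_fc differential-expression FDR and fold-change cutoffs.
#' @param decoy_min_score minimum duplex score for decoy sites.
#' @param rbh_min_score minimum Smith-Waterman score for ortholog hits.
#' @param sim a [sim_config()] controlling the synthetic dataset.
#' @param n_circs,alt_circ_genes,junction_reads,linear_depth synthetic
#'   planting scale.
#' @param n_tissues,n_specific tissue-profile scale.
#' @param de_fold_change,de_n_affected planted DE design.
#' @param n_orthologs,divergence planted proteome-pair design.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, anchor_length = 20L, min_reads = 2L,
                            max_dist = 100000L, max_mismatch = 2L,
                            tissue_index_cutoff = 0.9, de_fdr = 0.05,
                            de_fc = 2, decoy_min_score = 10,
                            rbh_min_score = 50,
                            sim = sim_config(seed = seed, n_chrom = 2L,
                                             chrom_length = 150000L,
                                             n_genes = 30L),
                            n_circs = 24L, alt_circ_genes = 3L,
                            junction_reads = 12L,
                            linear_depth = 8, n_tissues = 5L,
                            n_specific = 6L, de_fold_change = 4,
                            de_n_affected = 6L, n_orthologs = 15L,
                            divergence = 0.1) {
  structure(list(seed = as.integer(seed),
                 anchor_length = as.integer(anchor_length),
                 min_reads = as.integer(min_reads),
                 max_dist = as.integer(max_dist),
                 max_mismatch = as.integer(max_mismatch),
                 tissue_index_cutoff = tissue_index_cutoff,
                 de_fdr = de_fdr, de_fc = de_fc,
                 decoy_min_score = decoy_min_score,
                 rbh_min_score = rbh_min_score, sim = sim,
                 n_circs = as.integer(n_circs),
                 alt_circ_genes = as.integer(alt_circ_genes),
                 junction_reads = as.integer(junction_reads),
                 linear_depth = linear_depth,
                 n_tissues = as.integer(n_tissues),
                 n_specific = as.integer(n_specific),
                 de_fold_change = de_fold_change,
                 de_n_affected = as.integer(de_n_affected),
                 n_orthologs = as.integer(n_orthologs),
                 divergence = divergence),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `sim.<field>` keys set
#' the simulation sub-config. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (flags win).
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  sim_keys <- grep("^sim\\.", names(vals), value = TRUE)
  sim_args <- stats::setNames(vals[sim_keys], sub("^sim\\.", "", sim_keys))
  vals <- vals[setdiff(names(vals), sim_keys)]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_fmt("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (length(sim_args)) {
    if (!"seed" %in% names(sim_args) && "seed" %in% names(vals))
      sim_args$seed <- vals$seed
    vals$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config), file = f)
  unname(tools::md5sum(f))
}

provenance_header <- function(config) {
  ver <- tryCatch(as.character(utils::packageVersion("circseed")),
                  error = function(e) "dev")
  sprintf("# circseed %s | seed=%d | config=%s", ver, config$seed,
          config_hash(config))
}

write_tsv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV written by [run_all()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_prov <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)

#' Run the full pipeline end-to-end on synthetic data
#'
#' Stages: simulate -> detect -> annotate -> quantify -> tissue index ->
#' differential expression -> decoy prediction -> ceRNA network ->
#' conservation. All outputs are written as provenance-headed TSV (plus
#' BED/FASTA/GraphML/SIF) under `out_dir` and also returned invisibly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with all stage results.
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("circseed_"),
                    quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  stage <- function(name) say("[%s] %+5.1fs %s", format(Sys.time(), "%H:%M:%S"),
                              as.numeric(difftime(Sys.time(), t0, units = "secs")),
                              name)

  stage("simulate: reference, planted circRNAs, expression profiles")
  ref <- generate_reference(config$sim)
  write_genome(ref$genome, file.path(out_dir, "genome.fa"))
  write_annotation(ref$genes, file.path(out_dir, "genes.gff3"))
  circs_truth <- plant_circrnas(ref, n = config$n_circs,
                                alt_circ_genes = config$alt_circ_genes,
                                seed = config$seed)
  write_tsv_prov(circs_truth, file.path(out_dir, "truth_circs.tsv"), config)

  prof <- plant_expression_profiles(circs_truth$circ_id,
    n_tissues = config$n_tissues, n_specific = config$n_specific,
    de_pairs = list(list(pair = c("control", "treat"),
                         fold_change = config$de_fold_change,
                         n_affected = config$de_n_affected)),
    n_reps = config$sim$n_samples_per_condition, seed = config$seed)

  stage("simulate: per-tissue read sets")
  samples <- list()
  for (t in seq_len(config$n_tissues)) {
    tn <- colnames(prof$tissue_counts)[t]
    jr <- stats::setNames(prof$tissue_counts[, t], rownames(prof$tissue_counts))
    samples[[tn]] <- simulate_reads(ref, circs_truth, junction_reads = jr,
      linear_depth = config$linear_depth, read_length = config$sim$read_length,
      error_rate = config$sim$error_rate,
      anchor_length = config$anchor_length,
      seed = config$seed + t, sample_id = tn)[, c("read_id", "sequence")]
    write_fastq(samples[[tn]], file.path(out_dir, paste0(tn, ".fq")))
  }

  stage("detect: back-splice junction calling")
  det <- call_circrnas(samples, ref$genome, ref$genes,
                       min_reads = config$min_reads,
                       max_dist = config$max_dist,
                       anchor_length = config$anchor_length,
                       max_mismatch = config$max_mismatch)
  write_circ_bed(det$circs, file.path(out_dir, "circs.bed"))
  write_tsv_prov(det$circs, file.path(out_dir, "circs.tsv"), config)

  stage("annotate: positional classes and site labels")
  ann <- annotate_circs(det$circs, ref$genes, ref$lincrnas)
  write_tsv_prov(ann, file.path(out_dir, "annotation.tsv"), config)
  altc <- group_alternative_circularization(ann)

  stage("quantify: RPM, circular-to-linear ratio, parent RPKM")
  rpm_mat <- sweep(det$counts, 2, pmax(det$total_mapped, 1), "/") * 1e6
  lin_counts <- vapply(names(samples), function(sn)
    circ_linear_counts(det$circs, det$linear[[sn]]), numeric(nrow(det$circs)))
  if (nrow(det$circs) == 1L) lin_counts <- t(as.matrix(lin_counts))
  ratio <- circular_to_linear_ratio(det$counts, lin_counts)
  expr <- data.frame(circ_id = det$circs$circ_id,
                     mean_rpm = rowMeans(rpm_mat),
                     mean_ratio = rowMeans(ifelse(is.finite(ratio), ratio, NA)),
                     stringsAsFactors = FALSE)
  write_tsv_prov(cbind(expr, det$counts), file.path(out_dir, "expression.tsv"),
                 config)
  rpkm_mat <- vapply(names(samples), function(sn)
    gene_rpkm(ref$genes, det$linear[[sn]], max(det$total_mapped[[sn]], 1)),
    numeric(length(ref$genes)))

  stage("tissue: specificity index")
  tsi <- apply(rpm_mat, 1, tissue_specific_index)
  tsi_df <- data.frame(circ_id = det$circs$circ_id, tissue_index = tsi,
                       specific = !is.na(tsi) & tsi > config$tissue_index_cutoff,
                       stringsAsFactors = FALSE)
  write_tsv_prov(tsi_df, file.path(out_dir, "tissue_index.tsv"), config)

  stage("de: differential expression on planted count tables")
  de_in <- prof$de[[1]]
  ## nominal per-sample sequencing depth: junction counts are a vanishing
  ## fraction of a library, so totals are effectively equal across samples
  de <- differential_expression(de_in$counts, de_in$condition,
                                library_sizes = rep(1e6, ncol(de_in$counts)),
                                alpha = config$de_fdr, fc_cutoff = config$de_fc)
  write_tsv_prov(de, file.path(out_dir, "de.tsv"), config)

  stage("decoy: planted miRNAs and rule evaluation")
  exonic <- ann$circ_id[ann$is_exonic]
  circ_map <- det$circs[det$circs$circ_id %in% exonic, , drop = FALSE]
  circ_seqs <- stats::setNames(vapply(seq_len(nrow(circ_map)), function(i)
    circ_sequence(ref$genome, circ_map$chrom[i], circ_map$start[i],
                  circ_map$end[i], circ_map$strand[i]), character(1)),
    circ_map$circ_id)
  designs <- list(decoy_design(central_mm = 3, other_mm = 1),
                  decoy_design(central_mm = 2),
                  decoy_design(seed_mm = 1, central_mm = 3),
                  decoy_design(central_mm = 0))
  planted <- plant_decoy_sites(circ_seqs, designs, seed = config$seed)
  write_fasta(planted$mirnas, file.path(out_dir, "mirnas.fa"))
  dec <- predict_decoys(planted$mirnas, circ_seqs,
                        min_score = config$decoy_min_score)
  write_tsv_prov(dec$hits, file.path(out_dir, "decoys.tsv"), config)
  write_tsv_prov(dec$audit, file.path(out_dir, "decoy_audit.tsv"), config)

  stage("network: ceRNA graph")
  mrna_seqs <- stats::setNames(lapply(ref$genes[seq_len(min(10, length(ref$genes)))],
    function(g) transcript_sequence(ref$genome, g, g$transcripts[[1]])),
    names(ref$genes)[seq_len(min(10, length(ref$genes)))])
  mrna_seqs <- vapply(mrna_seqs, identity, character(1))
  targets <- predict_mrna_targets(planted$mirnas, mrna_seqs,
                                  min_score = config$decoy_min_score)
  net <- build_network(dec$hits, targets)
  export_network(net, file.path(out_dir, "network.graphml"), "graphml")
  export_network(net, file.path(out_dir, "network.sif"), "sif")

  stage("conserve: proteome pair, RBH, conserved circRNAs")
  pp <- generate_proteome_pair(n_orthologs = config$n_orthologs,
                               divergence = config$divergence,
                               seed = config$seed)
  orth <- reciprocal_best_hit(pp$proteome_a, pp$proteome_b,
                              min_score = config$rbh_min_score)
  write_tsv_prov(orth, file.path(out_dir, "orthologs.tsv"), config)
  ## mirror species: diverged copies of the detected circs on the planted
  ## ortholog partners (a synthetic stand-in for a second species' circ set).
  ## Reference genes are identified with proteome-A entries in order.
  n_map <- min(length(ref$genes), nrow(pp$ortholog_truth))
  map_a <- stats::setNames(pp$ortholog_truth$gene_a[seq_len(n_map)],
                           names(ref$genes)[seq_len(n_map)])
  map_b <- stats::setNames(pp$ortholog_truth$gene_b[seq_len(n_map)],
                           names(ref$genes)[seq_len(n_map)])
  parents <- ann$primary_parent
  circs_a <- data.frame(circ_id = ann$circ_id,
                        parent_gene = unname(map_a[parents]),
                        stringsAsFactors = FALSE)
  seqs_a <- stats::setNames(vapply(seq_len(nrow(det$circs)), function(i)
    circ_sequence(ref$genome, det$circs$chrom[i], det$circs$start[i],
                  det$circs$end[i], det$circs$strand[i]), character(1)),
    det$circs$circ_id)
  keep_a <- circs_a[!is.na(circs_a$parent_gene) &
                      !is.na(parents) & parents %in% names(map_b), , drop = FALSE]
  keep_parents <- parents[match(keep_a$circ_id, ann$circ_id)]
  circs_b <- data.frame(circ_id = paste0(keep_a$circ_id, "_sp2"),
                        parent_gene = unname(map_b[keep_parents]),
                        stringsAsFactors = FALSE)
  seqs_b <- stats::setNames(with_seed(config$seed + 11L, vapply(
    seqs_a[keep_a$circ_id], function(s)
      paste(apply_substitution_errors(s, 0.05), collapse = ""), character(1))),
    circs_b$circ_id)
  cons <- conserved_circrnas(circs_a, circs_b, orth, seqs_a, seqs_b)
  write_tsv_prov(cons, file.path(out_dir, "conserved.tsv"), config)

  stage("done")
  invisible(list(reference = ref, truth = list(circs = circs_truth,
                                               profiles = prof,
                                               decoys = planted$truth,
                                               orthologs = pp$ortholog_truth),
                 detection = det, annotation = ann, alt_circ = altc,
                 expression = list(rpm = rpm_mat, ratio = ratio,
                                   rpkm = rpkm_mat),
                 tissue = tsi_df, de = de, decoys = dec, targets = targets,
                 network = net, orthologs = orth, conserved = cons,
                 out_dir = out_dir))
}
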