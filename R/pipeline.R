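#' Configuration for a full pipeline run
#'
#' A run either simulates its cohort (`simulate = sim_config(...)`) or ingests
#' one from disk (`expression` TSV plus the signature files). All randomized
#' stages draw independent child seeds from `seed` by fixed offsets so single
#' stages can be rerun reproducibly.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master integer seed.
#' @param simulate A [sim_config()], or `NULL` to ingest from disk.
#' @param expression,scale Expression TSV path and its declared scale
#'   (ingest mode).
#' @param markers_gmt GMT whose first set holds the CAF marker genes
#'   (ingest mode).
#' @param reference_vectors_tsv Three-column TSV (gene, ne_value, nonne_value)
#'   for the NE score (ingest mode).
#' @param programs_gmt Optional GMT with sets `ne_program` and `nonne_program`
#'   for GSEA (ingest mode).
#' @param signatures_gmt Optional GMT with sets `stromal` and `immune`
#'   (ingest mode).
#' @param decon_reference_tsv Optional genes x cell-types profile TSV for the
#'   deconvolution estimator (ingest mode).
#' @param gep_weights_tsv Optional two-column TSV (gene, weight) enabling the
#'   T-cell-inflamed profile score.
#' @param external_abundance_csv Optional externally computed abundance CSV.
#' @param hallmark_gmt Optional signature library for the GSVA-style stage
#'   (simulate mode defaults to the generator's program sets).
#' @param drug_training Either `NULL` (simulate mode builds a fixture whose
#'   causal genes load on the fibroblast program), `FALSE` (skip the stage),
#'   or a list with `expression_tsv` and `response_csv` paths.
#' @param n_perm GSEA permutations (>= 100).
#' @param cluster_k Number of infiltration groups (2).
#'
#' @return A validated `run_config`.
#' @export
run_config <- function(outdir, seed, simulate = sim_config(),
                       expression = NULL, scale = c("linear", "log2p1"),
                       markers_gmt = NULL, reference_vectors_tsv = NULL,
                       programs_gmt = NULL, signatures_gmt = NULL,
                       decon_reference_tsv = NULL, gep_weights_tsv = NULL,
                       external_abundance_csv = NULL, hallmark_gmt = NULL,
                       drug_training = NULL, n_perm = 200, cluster_k = 2) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              expression = expression, scale = scale,
              markers_gmt = markers_gmt,
              reference_vectors_tsv = reference_vectors_tsv,
              programs_gmt = programs_gmt, signatures_gmt = signatures_gmt,
              decon_reference_tsv = decon_reference_tsv,
              gep_weights_tsv = gep_weights_tsv,
              external_abundance_csv = external_abundance_csv,
              hallmark_gmt = hallmark_gmt, drug_training = drug_training,
              n_perm = n_perm, cluster_k = cluster_k)
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$expression) || is.null(cfg$markers_gmt) ||
        is.null(cfg$reference_vectors_tsv)) {
      stop("ingest mode needs `expression`, `markers_gmt` and `reference_vectors_tsv`",
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(cfg$simulate, "sim_config"))
  }
  paths <- c(cfg$expression, cfg$markers_gmt, cfg$reference_vectors_tsv,
             cfg$programs_gmt, cfg$signatures_gmt, cfg$decon_reference_tsv,
             cfg$gep_weights_tsv, cfg$external_abundance_csv, cfg$hallmark_gmt,
             if (is.list(cfg$drug_training)) unlist(cfg$drug_training))
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing)) {
    stop("configured input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a two-column gene/weight TSV into a weighted gene set
#' @param path TSV with columns gene, weight.
#' @param name Set name.
#' @return A weighted [gene_set()].
#' @export
read_weight_table <- function(path, name = "weighted_set") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "weight") %in% names(tab)))
  gene_set(name, tab$gene, tab$weight)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: data (simulate or ingest), abundance estimation
#' (marker-mean, set-enrichment, deconvolution), composite clustering into
#' high/low infiltration groups, per-sample scores, group comparisons and
#' the CAF-abundance-vs-NE-score correlation, GSEA of the NE/Non-NE programs,
#' GSVA-style library scoring with moderated comparison, and (optionally) the
#' drug-sensitivity transfer stage. Every intermediate is written to
#' `config$outdir`; the run is deterministic given the seeds.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with the headline summary, output manifest,
#'   package version and config echo (also written as `run_report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- character()
  note <- function(f) manifest <<- c(manifest, f)
  skipped <- character()
  skip <- function(x) skipped <<- c(skipped, x)

  ## stage: data -------------------------------------------------------------
  dat <- run_stage("data", {
    if (!is.null(config$simulate)) {
      cohort <- simulate_cohort(config$simulate, seed = config$seed + 1L)
      prof <- cohort$profiles
      ne_genes <- cohort$memberships$ne_program$genes
      nonne_genes <- cohort$memberships$nonne_program$genes
      panel <- c(ne_genes, nonne_genes)
      list(
        expression = cohort$expression,
        markers = cohort$memberships$caf_markers,
        ref = reference_vectors(panel,
                                log2(prof[panel, "NE_tumor"] + 1),
                                log2(prof[panel, "NonNE_tumor"] + 1)),
        programs = signature_library(list(
          cohort$memberships$ne_program, cohort$memberships$nonne_program)),
        stromal = cohort$memberships$fibroblast_program,
        immune = cohort$memberships$immune_program,
        decon_ref = decon_reference(prof),
        library = if (is.null(config$hallmark_gmt)) cohort$memberships
                  else read_gmt(config$hallmark_gmt),
        cohort = cohort
      )
    } else {
      sigs <- if (!is.null(config$signatures_gmt)) read_gmt(config$signatures_gmt)
      list(
        expression = read_expression_matrix(config$expression, "tsv", config$scale),
        markers = read_gmt(config$markers_gmt)[[1]],
        ref = read_reference_vectors(config$reference_vectors_tsv),
        programs = if (!is.null(config$programs_gmt)) read_gmt(config$programs_gmt),
        stromal = if (!is.null(sigs)) sigs[["stromal"]],
        immune = if (!is.null(sigs)) sigs[["immune"]],
        decon_ref = if (!is.null(config$decon_reference_tsv)) {
          tab <- readr::read_tsv(config$decon_reference_tsv,
                                 show_col_types = FALSE, progress = FALSE)
          mat <- as.matrix(tab[-1]); rownames(mat) <- tab[[1]]
          decon_reference(mat)
        },
        library = if (!is.null(config$hallmark_gmt)) read_gmt(config$hallmark_gmt),
        cohort = NULL
      )
    }
  })
  expr <- dat$expression
  expr_log <- if (expr_scale(expr) == "linear") log_transform(expr, 1) else expr

  ## stage: abundance --------------------------------------------------------
  abundance <- run_stage("abundance", {
    ab <- marker_mean_score(expr_log, dat$markers)
    names(ab)[2] <- "Fibroblast_marker"
    ab$Fibroblast_enrich <- ssgsea_score(expr_log, dat$markers,
                                         alpha = 0.25, mode = "sum")$score
    if (!is.null(dat$decon_ref) && expr_scale(expr) == "linear") {
      dec <- nnls_deconvolution(expr, dat$decon_ref)
      fib <- dplyr::filter(dec, grepl("fibro", .data$cell_type, ignore.case = TRUE))
      if (nrow(fib)) {
        ab$Fibroblast_decon <- fib$fraction[match(ab$sample_id, fib$sample_id)]
      }
      imm <- dplyr::filter(dec, grepl("immune", .data$cell_type, ignore.case = TRUE))
      if (nrow(imm)) {
        ab$Immune_decon <- imm$fraction[match(ab$sample_id, imm$sample_id)]
      }
    }
    if (!is.null(config$external_abundance_csv)) {
      ext <- import_external_abundance(config$external_abundance_csv, expr)
      ab <- dplyr::left_join(ab, ext, by = "sample_id")
    }
    write_table(ab, out("abundance.csv"), "csv"); note("abundance.csv")
    ab
  })

  ## stage: clustering -------------------------------------------------------
  labeling <- run_stage("clustering", {
    fib_feats <- grep("^Fibroblast_", names(abundance), value = TRUE)
    composite <- build_caf_composite(expr_log, dat$markers, abundance,
                                     features = fib_feats)
    lab <- cluster_infiltration(composite, k = config$cluster_k)
    write_table(lab$labels, out("labels.csv"), "csv"); note("labels.csv")
    comp_df <- tibble::as_tibble(cbind(feature = rownames(composite),
                                       as.data.frame(composite)))
    write_table(comp_df, out("composite.tsv"), "tsv"); note("composite.tsv")
    lab
  })
  labels <- labeling$labels

  ## stage: scores -----------------------------------------------------------
  scores <- run_stage("scores", {
    sc <- ne_score(expr_log, dat$ref)
    if (all(c("GZMA", "PRF1") %in% rownames(expr)) && expr_scale(expr) == "linear") {
      sc <- dplyr::left_join(sc, cyt_score(expr), by = "sample_id")
    } else skip("cyt_score")
    if (!is.null(dat$immune)) {
      sc <- dplyr::left_join(sc, apm_score(expr_log, dat$immune), by = "sample_id")
    } else skip("apm_score")
    if (!is.null(config$gep_weights_tsv)) {
      gep <- read_weight_table(config$gep_weights_tsv, "gep")
      sc <- dplyr::left_join(sc, gep_score(expr_log, gep), by = "sample_id")
    } else skip("gep_score")
    if (all(c("ASCL1", "NEUROD1", "POU2F3", "YAP1") %in% rownames(expr))) {
      sub <- call_subtype(expr_log)
      sc <- dplyr::left_join(sc, sub[c("sample_id", "subtype")], by = "sample_id")
    } else skip("call_subtype")
    if (!is.null(dat$stromal) && !is.null(dat$immune)) {
      sc <- dplyr::left_join(sc, estimate_like_scores(expr_log, dat$stromal, dat$immune),
                             by = "sample_id")
    } else skip("estimate_like_scores")
    sc <- dplyr::left_join(sc, labels, by = "sample_id")
    write_table(sc, out("scores.csv"), "csv"); note("scores.csv")
    sc
  })

  ## stage: comparisons ------------------------------------------------------
  comparisons <- run_stage("comparisons", {
    grp <- check_group_labels(labels, scores$sample_id)
    rows <- list()
    score_cols <- intersect(c("ne_score", "cyt_score", "apm_score", "gep_score",
                              "stromal_score", "immune_score"), names(scores))
    for (col in score_cols) {
      ok <- !is.na(scores[[col]])
      tt <- group_tests(scores[[col]][ok], grp[ok], "welch_t")
      rows[[col]] <- tibble::tibble(
        quantity = col,
        mean_high = mean(scores[[col]][ok & grp == "high"]),
        mean_low = mean(scores[[col]][ok & grp == "low"]),
        statistic = tt$statistic, p_value = tt$p_value)
    }
    cmp <- dplyr::bind_rows(rows)
    corr <- pearson_correlation(abundance$Fibroblast_marker, scores$ne_score)
    cmp <- dplyr::bind_rows(cmp, tibble::tibble(
      quantity = "cor_caf_abundance_vs_ne_score",
      mean_high = NA, mean_low = NA,
      statistic = corr$estimate, p_value = corr$p_value))
    write_table(cmp, out("comparisons.csv"), "csv"); note("comparisons.csv")
    cmp
  })

  ## stage: gsea -------------------------------------------------------------
  gsea <- run_stage("gsea", {
    if (is.null(dat$programs)) {
      skip("gsea"); NULL
    } else {
      res <- purrr::imap_dfr(dat$programs, function(s, nm) {
        tidy(gsea_nes(expr_log, labels, s, n_perm = config$n_perm,
                      seed = config$seed + 2L))
      })
      write_table(res, out("gsea.csv"), "csv"); note("gsea.csv")
      res
    }
  })

  ## stage: library comparison ----------------------------------------------
  gsva_cmp <- run_stage("gsva_comparison", {
    if (is.null(dat$library)) {
      skip("gsva_comparison"); NULL
    } else {
      sv <- gsva_like_scores(expr_log, dat$library)
      fit <- moderated_t(sv, labels)
      write_table(tidy(fit), out("gsva_comparison.csv"), "csv")
      note("gsva_comparison.csv")
      fit
    }
  })

  ## stage: drugs ------------------------------------------------------------
  drug_cmp <- run_stage("drugs", {
    if (isFALSE(config$drug_training)) {
      skip("drugs"); NULL
    } else if (is.list(config$drug_training)) {
      train <- read_expression_matrix(config$drug_training$expression_tsv,
                                      "tsv", "log2p1")
      resp <- readr::read_csv(config$drug_training$response_csv,
                              show_col_types = FALSE, progress = FALSE)
      preds <- purrr::map_dfr(split(resp, resp$drug), function(dd) {
        mdl <- fit_ridge_transfer(train[, dd$line, drop = FALSE],
                                  stats::setNames(dd$value, dd$line),
                                  seed = config$seed + 3L, drug = dd$drug[1])
        predict_sensitivity(mdl, expr_log)
      })
      cmp <- compare_sensitivity(preds, labels)
      write_table(preds, out("sensitivity.csv"), "csv"); note("sensitivity.csv")
      write_table(cmp, out("drug_comparison.csv"), "csv"); note("drug_comparison.csv")
      cmp
    } else if (!is.null(dat$cohort)) {
      # fixture: one drug whose causal genes load on the fibroblast program
      # (positive weights: fibroblast-rich tumours get higher predicted IC50),
      # one with causal genes off-program as a control
      genes <- rownames(expr)
      fib_genes <- dat$cohort$memberships$fibroblast_program$genes
      other <- setdiff(genes, fib_genes)[seq_len(min(89, length(genes) - length(fib_genes)))]
      universe <- c(fib_genes, other)
      causal_sets <- list(fibro_drug = fib_genes,
                          control_drug = other[seq_len(min(10, length(other)))])
      preds <- dplyr::bind_rows(purrr::imap(causal_sets, function(causal, nm) {
        tr <- simulate_drug_training(
          n_lines = 60, n_genes = length(universe), n_causal = length(causal),
          noise_sd = 0.5, seed = config$seed + 3L + (nm == "control_drug"),
          gene_ids = universe, causal_genes = causal, causal_sign = "positive")
        mdl <- fit_ridge_transfer(tr$expression, tr$response,
                                  seed = config$seed + 4L, drug = nm)
        predict_sensitivity(mdl, expr_log)
      }))
      cmp <- compare_sensitivity(preds, labels)
      write_table(preds, out("sensitivity.csv"), "csv"); note("sensitivity.csv")
      write_table(cmp, out("drug_comparison.csv"), "csv"); note("drug_comparison.csv")
      cmp
    } else {
      skip("drugs"); NULL
    }
  })

  ## report ------------------------------------------------------------------
  grp <- check_group_labels(labels, scores$sample_id)
  summary <- list(
    n_samples = ncol(expr), n_genes = nrow(expr),
    group_sizes = as.list(table(grp)),
    mean_ne_score = list(high = mean(scores$ne_score[grp == "high"], na.rm = TRUE),
                         low = mean(scores$ne_score[grp == "low"], na.rm = TRUE)),
    caf_vs_ne_correlation = comparisons$statistic[
      comparisons$quantity == "cor_caf_abundance_vs_ne_score"],
    nes = if (!is.null(gsea)) stats::setNames(as.list(gsea$nes), gsea$set),
    drug_directions = if (!is.null(drug_cmp)) as.list(table(drug_cmp$direction)),
    skipped_stages = skipped
  )
  manifest <- c(manifest, "run_report.json")
  report <- list(summary = summary, manifest = manifest,
                 version = as.character(utils::packageVersion("sclcaf")),
                 config = config[setdiff(names(config), "simulate")],
                 sim_config = if (!is.null(config$simulate)) unclass(config$simulate))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  structure(c(report, list(labels = labels, scores = scores, gsea = gsea,
                           comparisons = comparisons)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<run_report> %d samples, %d genes; high/low = %s/%s\n",
              s$n_samples, s$n_genes, s$group_sizes$high, s$group_sizes$low))
  cat(sprintf("  mean NE score: high %.3f, low %.3f; CAF~NE cor r = %.3f\n",
              s$mean_ne_score$high, s$mean_ne_score$low, s$caf_vs_ne_correlation))
  if (!is.null(s$nes)) {
    cat("  NES:", paste(sprintf("%s = %.2f", names(s$nes), unlist(s$nes)),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
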