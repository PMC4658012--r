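#' End-to-end workflows
#'
#' Two orchestrated pipelines tie the modules together: a binding pipeline
#' (sequences -> score matrices -> AUC cutoff sweep -> filtered report) and
#' an expression pipeline (TSS table -> regions, optionally chromatin
#' refined -> TBA/occupancy design -> normalization -> OLS / CV / lasso /
#' controls).  Intermediate score matrices are always written so either
#' pipeline can be resumed or inspected mid-way, and every run leaves a
#' provenance sidecar (configuration hash, seed, package version).
#'
#' @name pipelines
NULL

#' Assemble a run configuration
#'
#' @param ... named configuration entries (input paths or in-memory objects,
#'   cutoff grid, seeds, `out_dir`).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  for (f in c("pos_fasta", "neg_fasta", "pwm_dir", "genome", "tss",
              "chromhmm", "expr")) {
    v <- cfg[[f]]
    looks_like_path <- is.character(v) && length(v) == 1L &&
      is.null(names(v)) && !grepl("^[ACGTNacgtn]+$", v)
    if (looks_like_path && !file.exists(v))
      stopf("configured %s file does not exist: %s", f, v)
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  flat <- utils::capture.output(utils::str(cfg, digits.d = 12))
  as.character(sum(utf8ToInt(paste(flat, collapse = "\n")) *
                     seq_along(utf8ToInt(paste(flat, collapse = "\n")))) %%
                 .Machine$integer.max)
}

write_provenance <- function(out_dir, cfg, what) {
  prov <- list(what = what,
               config_hash = config_hash(cfg),
               seed = cfg$seed %||% NA,
               package = "affinityscan",
               version = as.character(utils::packageVersion("affinityscan")))
  jsonlite::write_json(prov, file.path(out_dir, paste0(what, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

resolve_pwms <- function(cfg) {
  if (!is.null(cfg$pwms)) return(cfg$pwms)
  if (!is.null(cfg$pwm_dir))
    return(read_pwm_dir(cfg$pwm_dir, kind = cfg$pwm_kind %||% "counts"))
  stopf("configuration needs 'pwms' (list) or 'pwm_dir' (directory)")
}

resolve_bg <- function(cfg) {
  if (is.null(cfg$bg)) background()
  else if (inherits(cfg$bg, "background")) cfg$bg
  else if (is.character(cfg$bg)) background_from_fasta(cfg$bg)
  else background(cfg$bg)
}

#' Run the binding-evaluation pipeline
#'
#' Scores positive and negative sequence sets against every PWM, sweeps the
#' occupancy cutoff grid, filters uninformative pairs and writes TSV
#' reports (`auc_sweep.tsv`, `auc_filtered.tsv`, `auc_by_pwm.tsv`) plus the
#' TBA score matrices of both classes.
#'
#' @param cfg a [run_config()] with `pos_fasta`/`neg_fasta` (FASTA paths or
#'   record lists), `pwms` or `pwm_dir`, optional `bg`, `grid`, `out_dir`.
#' @return The filtered AUC data frame, invisibly; files under
#'   `cfg$out_dir`.
#' @export
run_binding_pipeline <- function(cfg) {
  pwms <- resolve_pwms(cfg)
  bg <- resolve_bg(cfg)
  grid <- cfg$grid %||% cutoff_grid()
  pos <- if (is.character(cfg$pos_fasta)) read_fasta_records(cfg$pos_fasta)
         else cfg$pos_fasta
  neg <- if (is.character(cfg$neg_fasta)) read_fasta_records(cfg$neg_fasta)
         else cfg$neg_fasta
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_score_matrix(score_matrix(pwms, pos, bg, mode = "tba"),
                     file.path(out_dir, "tba_positives.tsv"))
  write_score_matrix(score_matrix(pwms, neg, bg, mode = "tba"),
                     file.path(out_dir, "tba_negatives.tsv"))
  sweep <- cutoff_sweep(pwms, list(positives = pos, negatives = neg),
                        bg, grid)
  filtered <- filter_uninformative(sweep)
  utils::write.table(sweep, file.path(out_dir, "auc_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filtered, file.path(out_dir, "auc_filtered.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(average_auc(filtered),
                     file.path(out_dir, "auc_by_pwm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, cfg, "binding")
  invisible(filtered)
}

#' Run the expression-modelling pipeline
#'
#' Builds regulatory regions from a TSS table (chromatin-refined when a
#' segmentation is supplied), computes the TBA design matrix (and an
#' occupancy design at `cfg$cutoff` for comparison), normalizes raw
#' expression, and fits the OLS model with 10-fold CV; optionally also the
#' lasso and the shuffled-PWM control.  Writes `design_tba.tsv`,
#' `coefficients.tsv` and `fit_summary.json`.
#'
#' @param cfg a [run_config()] with `tss` (BED6 path or data frame),
#'   `genome` (FASTA path or named vector), `pwms`/`pwm_dir`, `expr` (TSV
#'   path gene/value or named vector of raw expression), and optionally
#'   `chromhmm` (+`state_map`), `up`, `down`, `cutoff`, `lasso`,
#'   `shuffle_control`, `seed`, `out_dir`.
#' @return List with the fitted objects, invisibly; files under
#'   `cfg$out_dir`.
#' @export
run_expression_pipeline <- function(cfg) {
  pwms <- resolve_pwms(cfg)
  bg <- resolve_bg(cfg)
  seed <- cfg$seed %||% 1
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tss <- if (is.character(cfg$tss)) read_tss_bed(cfg$tss) else cfg$tss
  regions <- lapply(seq_len(nrow(tss)), function(i)
    promoter_from_tss(tss[i, ], up = cfg$up %||% 1500,
                      down = cfg$down %||% 500))
  if (!is.null(cfg$chromhmm)) {
    segs <- if (is.character(cfg$chromhmm))
      read_segmentation_bed(cfg$chromhmm,
                            cfg$state_map %||% read_state_map())
      else cfg$chromhmm
    regions <- lapply(regions, refine_with_chromatin, segments = segs)
  }
  recs <- extract_sequences(regions, cfg$genome)
  design <- score_matrix(pwms, recs, bg, mode = "tba")
  write_score_matrix(design, file.path(out_dir, "design_tba.tsv"))
  raw <- cfg$expr
  if (is.character(raw)) {
    tab <- utils::read.table(raw, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    raw <- setNames(tab[[2]], tab[[1]])
  }
  expr <- normalize_expression(raw)
  fit <- fit_linear(design, expr)
  cv <- crossval_r2(design, expr, folds = cfg$cv %||% 10, seed = seed)
  result <- list(fit = fit, cv_r2 = cv, skipped = attr(recs, "skipped"))
  if (!is.null(cfg$cutoff)) {
    occ_design <- score_matrix(pwms, recs, bg, mode = "occupancy",
                               cutoff = cfg$cutoff)
    write_score_matrix(occ_design,
                       file.path(out_dir,
                                 sprintf("design_occupancy_%g.tsv",
                                         cfg$cutoff)))
    result$fit_occupancy <- fit_linear(occ_design, expr)
  }
  if (isTRUE(cfg$lasso))
    result$lasso <- fit_lasso(design, expr, seed = seed)
  if (isTRUE(cfg$shuffle_control))
    result$shuffle <- shuffled_pwm_control(pwms, recs, expr, bg, seed = seed)
  co <- summary(fit)$coefficients
  utils::write.table(data.frame(term = rownames(co), co,
                                check.names = FALSE),
                     file.path(out_dir, "coefficients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(n_genes = fit$n_genes, n_predictors = fit$n_predictors,
               r2 = fit$r2, adj_r2 = fit$adj_r2, p = fit$p, cv_r2 = cv,
               dropped_genes = fit$dropped,
               skipped_regions = attr(recs, "skipped"))
  if (!is.null(result$fit_occupancy))
    summ$adj_r2_occupancy <- result$fit_occupancy$adj_r2
  if (!is.null(result$lasso)) {
    summ$lasso_selected <- length(result$lasso$selected)
    summ$lasso_cv_r2 <- result$lasso$cv_r2
  }
  if (!is.null(result$shuffle)) {
    summ$r2_shuffled <- unname(result$shuffle$r2_shuffled)
    summ$shuffle_p <- result$shuffle$p
  }
  jsonlite::write_json(summ, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(out_dir, cfg, "expression")
  invisible(result)
}
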