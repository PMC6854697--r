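# End-to-end pipeline: encode -> similarity -> fuse -> score -> evaluate.
#
# A flat validated config drives the run; every artifact (fused matrices,
# DDA matrix, evaluation report, resolved config, log) is written to the
# output directory, and re-running with an identical config and seed
# reproduces all outputs byte-for-byte.

#' Encode drug features into a profile bundle
#'
#' @param smiles named character vector of SMILES strings (or NULL)
#' @param targets,enzymes named lists of per-drug sequence vectors (or
#'   NULL)
#' @param expression an \code{\link{expression_table}} (or NULL)
#' @param ngram_table k-gram embedding table; defaults to the built-in
#'   seeded table
#' @param dgep_encoding \code{"autoencoder"} (bottleneck activations of a
#'   trained auto-encoder) or \code{"raw"} (full-gene dGEP vectors)
#' @param ae_config auto-encoder configuration used when
#'   \code{dgep_encoding = "autoencoder"}
#' @param seed integer seed (used for the default ngram table and the
#'   auto-encoder)
#' @return a \code{\link{drug_profiles}} object; when an auto-encoder was
#'   trained it is attached as attribute \code{autoencoder}
#' @export
encode_drug_profiles <- function(smiles = NULL, targets = NULL, enzymes = NULL,
                                 expression = NULL, ngram_table = NULL,
                                 dgep_encoding = c("autoencoder", "raw"),
                                 ae_config = NULL, seed = 1L) {
  dgep_encoding <- match.arg(dgep_encoding)
  s_mat <- if (!is.null(smiles)) encode_smiles_table(smiles) else NULL
  p_sets <- e_sets <- NULL
  if (!is.null(targets) || !is.null(enzymes)) {
    ngram_table <- ngram_table %||%
      ngram_embedding_table(seed = derive_seed(seed, "ngram-table"))
    if (!is.null(targets)) p_sets <- embed_sequence_sets(targets, ngram_table)
    if (!is.null(enzymes)) e_sets <- embed_sequence_sets(enzymes, ngram_table)
  }
  g_mat <- NULL; ae <- NULL
  if (!is.null(expression)) {
    dgeps <- compute_dgep_matrix(expression)
    if (dgep_encoding == "autoencoder") {
      ae_config <- ae_config %||% autoencoder_config(
        layer_units = c(64L, 20L, 64L), activations = "linear",
        epochs = 30L, batch_size = 32L,
        seed = derive_seed(seed, "autoencoder"))
      ae <- train_dgep_autoencoder(dgeps, ae_config)
      g_mat <- encode_dgep(ae, dgeps)
      rownames(g_mat) <- rownames(dgeps)
    } else {
      g_mat <- dgeps
    }
  }
  out <- drug_profiles(smiles = s_mat, targets = p_sets, enzymes = e_sets,
                       dgep = g_mat)
  attr(out, "autoencoder") <- ae
  out
}

#' Build a validated pipeline configuration
#'
#' @param smiles,targets,enzymes,expression,expression_meta,phenotype,genotype,associations
#'   input file paths (an input may be NULL when the feature subset does
#'   not need it)
#' @param features drug feature subset, nonempty subset of
#'   \code{c("s", "p", "e", "g")}
#' @param mode Eq.-1 exclusion mode: \code{"strict"}, \code{"pair"} or
#'   \code{"none"}
#' @param n_pheno,n_geno PCA components for the disease features
#' @param dgep_encoding \code{"autoencoder"} or \code{"raw"}
#' @param fraction,repeats sampled-AUC parameters
#' @param k cross-validation folds
#' @param seed master seed for every stochastic stage
#' @param out_dir output directory
#' @param expression_logged whether the expression values are already
#'   log2-scaled
#' @return validated config list of class \code{pipeline_config}
#' @export
pipeline_config <- function(smiles = NULL, targets = NULL, enzymes = NULL,
                            expression = NULL, expression_meta = NULL,
                            phenotype = NULL, genotype = NULL,
                            associations = NULL,
                            features = c("s", "p", "e", "g"),
                            mode = "strict",
                            n_pheno = 30L, n_geno = 20L,
                            dgep_encoding = "autoencoder",
                            fraction = 0.10, repeats = 20L, k = 5L,
                            seed = 1L, out_dir = NULL,
                            expression_logged = TRUE) {
  abort_if(length(features) == 0 || !all(features %in% c("s", "p", "e", "g")),
           "features must be a nonempty subset of {s, p, e, g}")
  abort_if(!mode %in% c("strict", "pair", "none"), "invalid mode '%s'", mode)
  need <- c(s = "smiles", p = "targets", e = "enzymes", g = "expression")[features]
  cfg <- list(smiles = smiles, targets = targets, enzymes = enzymes,
              expression = expression, expression_meta = expression_meta,
              phenotype = phenotype, genotype = genotype,
              associations = associations,
              features = sort(features), mode = mode,
              n_pheno = as.integer(n_pheno), n_geno = as.integer(n_geno),
              dgep_encoding = dgep_encoding,
              fraction = fraction, repeats = as.integer(repeats),
              k = as.integer(k), seed = as.integer(seed),
              out_dir = out_dir, expression_logged = expression_logged)
  for (f in unname(need)) {
    abort_if(is.null(cfg[[f]]), "feature subset requires input '%s'", f)
  }
  if ("g" %in% features) {
    abort_if(is.null(cfg$expression_meta), "expression input requires expression_meta")
  }
  for (f in c("phenotype", "genotype", "associations")) {
    abort_if(is.null(cfg[[f]]), "input '%s' is required", f)
  }
  paths <- unlist(cfg[c("smiles", "targets", "enzymes", "expression",
                        "expression_meta", "phenotype", "genotype",
                        "associations")])
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  abort_if(length(missing) > 0, "input file(s) not found: %s",
           paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Reads the configured inputs, encodes drug and disease features, builds
#' the fused DDSI and DiDiS matrices, scores every drug-disease pair and
#' runs the evaluation protocols. All artifacts are written to
#' \code{config$out_dir} (ddsi.tsv, didis.tsv, dda.tsv, report.json,
#' config.json, pipeline.log).
#'
#' @param config a \code{\link{pipeline_config}}
#' @return invisibly, a list with the fused matrices, the DDA matrix, the
#'   leave-one-out result and the evaluation reports
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must come from pipeline_config()")
  out_dir <- config$out_dir %||% tempfile("reposim_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[reposim] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, log_path)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("read", {
    list(smiles = if (!is.null(config$smiles)) read_smiles_table(config$smiles),
         targets = if (!is.null(config$targets)) read_grouped_fasta(config$targets),
         enzymes = if (!is.null(config$enzymes)) read_grouped_fasta(config$enzymes),
         expression = if (!is.null(config$expression))
           read_expression_table(config$expression, config$expression_meta,
                                 logged = config$expression_logged),
         phenotype = read_term_annotations(config$phenotype),
         genotype = read_term_annotations(config$genotype),
         associations = read_associations(config$associations))
  })
  say("read: %d drugs (smiles), %d diseases (phenotype), %d known associations",
      length(inputs$smiles %||% character()),
      length(inputs$phenotype), nrow(inputs$associations))

  profiles <- stage("encode-drugs", {
    encode_drug_profiles(smiles = inputs$smiles,
                         targets = inputs$targets,
                         enzymes = inputs$enzymes,
                         expression = inputs$expression,
                         dgep_encoding = config$dgep_encoding,
                         seed = config$seed)
  })
  disease_enc <- stage("encode-diseases", {
    encode_diseases(inputs$phenotype, inputs$genotype,
                    n_pheno = config$n_pheno, n_geno = config$n_geno)
  })
  say("encode: drug features {%s}; %d diseases with both feature types",
      paste(config$features, collapse = ","), nrow(disease_enc$phenotype))

  ddsi <- stage("ddsi", suppressMessages(build_ddsi(profiles, config$features)))
  didis <- stage("didis", build_didis(disease_enc$phenotype, disease_enc$genotype))
  say("similarity: DDSI %dx%d (dropped %d), DiDiS %dx%d",
      nrow(ddsi), ncol(ddsi), attr(ddsi, "n_dropped") %||% 0L,
      nrow(didis), ncol(didis))

  A <- inputs$associations
  A <- A[A$drug %in% rownames(ddsi) & A$disease %in% rownames(didis), , drop = FALSE]
  say("score: %d resolvable known associations (mode %s)", nrow(A), config$mode)
  dda <- stage("score", score_all(ddsi, didis, A, config$mode))
  loo <- stage("evaluate-loo", loo_scores(ddsi, didis, A, config$mode))
  reports <- stage("evaluate", {
    suppressMessages(list(
      loo_full_auc = loo_full_auc(loo),
      sampled = sampled_auc(loo, fraction = config$fraction,
                            repeats = config$repeats, seed = config$seed),
      per_disease = tryCatch(per_entity_auc(loo, "disease"), error = function(e) NULL),
      per_drug = tryCatch(per_entity_auc(loo, "drug"), error = function(e) NULL),
      kfold = kfold_cv(ddsi, didis, A, k = config$k, mode = config$mode,
                       seed = config$seed)))
  })
  say("evaluate: LOO AUC %.4f, sampled AUC %.4f, %d-fold AUC %.4f",
      reports$loo_full_auc, reports$sampled$auc_mean, config$k,
      reports$kfold$auc_mean)

  stage("write", {
    write_matrix(unclass(ddsi), file.path(out_dir, "ddsi.tsv"),
                 comment = sprintf("DDSI features=%s min_const=%.15g max_const=%.15g",
                                   paste(attr(ddsi, "features"), collapse = ","),
                                   attr(ddsi, "min_const"), attr(ddsi, "max_const")))
    write_matrix(unclass(didis), file.path(out_dir, "didis.tsv"),
                 comment = sprintf("DiDiS min_const=%.15g max_const=%.15g",
                                   attr(didis, "min_const"), attr(didis, "max_const")))
    write_matrix(unclass(dda), file.path(out_dir, "dda.tsv"),
                 comment = sprintf("DDA mode=%s", attr(dda, "mode")))
    report_json <- list(
      loo_full_auc = reports$loo_full_auc,
      sampled_auc_mean = reports$sampled$auc_mean,
      sampled_auc_values = reports$sampled$auc_values,
      per_disease_auc_mean = if (!is.null(reports$per_disease))
        reports$per_disease$auc_mean else NA,
      per_drug_auc_mean = if (!is.null(reports$per_drug))
        reports$per_drug$auc_mean else NA,
      kfold_auc_mean = reports$kfold$auc_mean,
      kfold_auc_values = reports$kfold$auc_values,
      n_drugs = nrow(ddsi), n_diseases = nrow(didis),
      n_known = nrow(A), n_unknown = sum(!loo$known_mask),
      features = config$features, mode = config$mode, seed = config$seed)
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_plain <- unclass(config)
    cfg_plain$out_dir <- NULL   # snapshot is location-independent
    jsonlite::write_json(cfg_plain, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, log_path)
  })

  invisible(list(ddsi = ddsi, didis = didis, dda = dda, loo = loo,
                 reports = reports, out_dir = out_dir))
}
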