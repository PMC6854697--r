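# Seeded synthetic-data generators.
#
# The cohort generator plants a cluster structure shared by every
# modality: each drug and disease belongs to one of n_clusters therapeutic
# clusters and carries a within-cluster gradient position t in [0, 1].
# Raw modalities are synthesised consistently with that latent structure -
# SMILES strings and amino-acid sequences as cluster templates mutated
# along a fixed per-cluster mutation path (depth proportional to t and to
# noise_sd), expression profiles as a cluster signature plus a gradient
# term, and disease term sets as a sliding window over an ordered
# per-cluster term list. Associations are planted within clusters between
# gradient-matched drug-disease pairs, so the similarity structure the
# pipeline must recover is present in every feature, and noise_sd = 0
# collapses each cluster to identical entities. All corruption rates
# scale with noise_sd; all randomness derives from one seed via named
# sub-streams, so the same seed yields byte-identical files.

smiles_template_chars <- function() {
  c("C", "c", "N", "n", "O", "o", "S", "=", "#", "(", ")", "1", "2", "3", "F", "P")
}

# mutate a template character vector: the first n_grad positions of the
# cluster's mutation path, plus iid substitutions at rate `rate`
mutate_template <- function(template, path_pos, path_repl, n_grad, rate, chars) {
  s <- template
  if (n_grad > 0) {
    take <- seq_len(min(n_grad, length(path_pos)))
    s[path_pos[take]] <- path_repl[take]
  }
  hit <- stats::runif(length(s)) < rate
  if (any(hit)) s[hit] <- sample(chars, sum(hit), replace = TRUE)
  paste(s, collapse = "")
}

#' Generate a synthetic drug-disease cohort
#'
#' Produces every raw input the pipeline consumes (SMILES table, grouped
#' target and enzyme FASTA, log2 expression table with replicate/control
#' metadata, phenotype and genotype term annotations, known association
#' list), with cluster-plus-gradient structure planted consistently
#' across all modalities and associations connecting gradient-matched
#' drug-disease pairs of the same cluster.
#'
#' @param n_drugs,m_diseases cohort sizes
#' @param n_clusters number of planted clusters (<= both cohort sizes)
#' @param assoc_per_cluster planted associations per cluster (default 50,
#'   i.e. about 2.5 indications per drug on the default cohort sizes,
#'   the density typical of curated indication catalogues)
#' @param noise_sd master noise level >= 0; scales mutation depths,
#'   expression noise and term corruption (0 = identical entities within
#'   a cluster)
#' @param seed integer seed; the same seed reproduces the cohort (and its
#'   files) byte-identically
#' @param dir optional directory; when given, all modalities are written
#'   as the text files the readers in this package parse
#' @param shuffle_labels if TRUE, disease cluster labels are permuted
#'   before planting associations (features keep their true structure),
#'   removing the signal the method exploits - a negative control
#' @return object of class \code{synthetic_cohort}: list with the raw
#'   modalities, the planted \code{associations}, \code{clusters} and
#'   \code{gradient} assignments, and \code{files} (paths, when written)
#' @export
generate_cohort <- function(n_drugs = 100L, m_diseases = 50L, n_clusters = 5L,
                            assoc_per_cluster = 50L, noise_sd = 0.1,
                            seed = 1L, dir = NULL, shuffle_labels = FALSE) {
  abort_if(n_clusters > min(n_drugs, m_diseases),
           "n_clusters must not exceed min(n_drugs, m_diseases)")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  drug_ids <- sprintf("DR%03d", seq_len(n_drugs))
  dis_ids <- sprintf("DI%03d", seq_len(m_diseases))
  drug_cl <- rep_len(seq_len(n_clusters), n_drugs)
  dis_cl <- rep_len(seq_len(n_clusters), m_diseases)
  drug_t <- with_seed(derive_seed(seed, "drug-gradient"), stats::runif(n_drugs))
  dis_t <- with_seed(derive_seed(seed, "disease-gradient"), stats::runif(m_diseases))

  chars <- smiles_template_chars()
  smi_len <- 60L; path_len <- 30L
  cl_templates <- with_seed(derive_seed(seed, "smiles-templates"), {
    lapply(seq_len(n_clusters), function(c) {
      list(template = sample(chars, smi_len, replace = TRUE),
           pos = sample.int(smi_len, path_len),
           repl = sample(chars, path_len, replace = TRUE))
    })
  })
  smiles <- with_seed(derive_seed(seed, "smiles"), {
    vapply(seq_len(n_drugs), function(i) {
      tp <- cl_templates[[drug_cl[i]]]
      mutate_template(tp$template, tp$pos, tp$repl,
                      n_grad = round(drug_t[i] * noise_sd * 4 * smi_len),
                      rate = 0.05 * noise_sd, chars = chars)
    }, character(1))
  })
  names(smiles) <- drug_ids

  make_seq_modality <- function(label, n_templates = 2L) {
    seq_len_aa <- 90L; seq_path <- 45L
    aa <- aa_alphabet(include_x = FALSE)
    tmpl <- with_seed(derive_seed(seed, paste0(label, "-templates")), {
      lapply(seq_len(n_clusters), function(c) {
        lapply(seq_len(n_templates), function(k) {
          list(template = sample(aa, seq_len_aa, replace = TRUE),
               pos = sample.int(seq_len_aa, seq_path),
               repl = sample(aa, seq_path, replace = TRUE))
        })
      })
    })
    with_seed(derive_seed(seed, label), {
      out <- lapply(seq_len(n_drugs), function(i) {
        # every drug carries one sequence per cluster template, so set
        # similarity reflects sequence content, not set cardinality
        vapply(seq_len(n_templates), function(s) {
          tp <- tmpl[[drug_cl[i]]][[s]]
          mutate_template(tp$template, tp$pos, tp$repl,
                          n_grad = round(drug_t[i] * noise_sd * 4 * seq_len_aa),
                          rate = 0.05 * noise_sd, chars = aa)
        }, character(1))
      })
      stats::setNames(out, drug_ids)
    })
  }
  targets <- make_seq_modality("targets")
  enzymes <- make_seq_modality("enzymes")

  n_genes <- 200L
  expr <- with_seed(derive_seed(seed, "expression"), {
    genes <- sprintf("G%04d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 1)
    base_sig <- matrix(stats::rnorm(n_genes * n_clusters), n_genes, n_clusters)
    grad_dir <- matrix(stats::rnorm(n_genes * n_clusters), n_genes, n_clusters)
    n_ctrl <- 4L; n_rep <- 2L
    cols <- list(); meta <- list()
    for (r in seq_len(n_ctrl)) {
      sid <- sprintf("CTRL_%d", r)
      cols[[sid]] <- baseline + stats::rnorm(n_genes, sd = 0.5 * noise_sd)
      meta[[sid]] <- data.frame(sample_id = sid, drug_id = "CONTROL",
                                cell_line = "CL1", replicate = r)
    }
    for (i in seq_len(n_drugs)) {
      sig <- base_sig[, drug_cl[i]] + (drug_t[i] - 0.5) * 8 * noise_sd * grad_dir[, drug_cl[i]]
      for (r in seq_len(n_rep)) {
        sid <- sprintf("%s_%d", drug_ids[i], r)
        cols[[sid]] <- baseline + sig + stats::rnorm(n_genes, sd = 0.3 * noise_sd)
        meta[[sid]] <- data.frame(sample_id = sid, drug_id = drug_ids[i],
                                  cell_line = "CL1", replicate = r)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- genes
    expression_table(vals, do.call(rbind, meta), logged = TRUE)
  })

  make_terms <- function(label, prefix) {
    list_len <- 40L; win <- 20L
    with_seed(derive_seed(seed, label), {
      vocab_by_cl <- lapply(seq_len(n_clusters), function(c)
        sprintf("%s%d_%02d", prefix, c, seq_len(list_len)))
      all_terms <- unlist(vocab_by_cl)
      ann <- lapply(seq_len(m_diseases), function(j) {
        v <- vocab_by_cl[[dis_cl[j]]]
        start <- round(dis_t[j] * noise_sd * 100)
        start <- min(start, list_len - win)
        terms <- v[(start + 1):(start + win)]
        keep <- stats::runif(win) >= 0.1 * noise_sd        # random drops
        extra <- all_terms[stats::runif(length(all_terms)) < 0.002 * noise_sd]
        sort(unique(c(terms[keep], extra)), method = "radix")
      })
      stats::setNames(ann, dis_ids)
    })
  }
  phenotype <- make_terms("phenotype", "P")
  genotype <- make_terms("genotype", "G")

  assoc <- with_seed(derive_seed(seed, "associations"), {
    eff_cl <- dis_cl; eff_t <- dis_t
    eff_dcl <- drug_cl; eff_dt <- drug_t
    if (shuffle_labels) {
      # permute both sides so planted pairs carry no feature signal at
      # all: co-indicated drugs are then no more similar than random
      perm <- sample.int(m_diseases)
      eff_cl <- dis_cl[perm]; eff_t <- dis_t[perm]
      perm_d <- sample.int(n_drugs)
      eff_dcl <- drug_cl[perm_d]; eff_dt <- drug_t[perm_d]
    }
    # Rank-matched round-robin planting: within each cluster, drugs and
    # diseases are ordered by gradient position and paired rank-to-rank,
    # later rounds shifting the disease rank by +-1, +-2, ... Every drug
    # and disease therefore ends up with a near-equal number of
    # associations (multi-indication drugs with homogeneous degrees, as
    # in curated indication catalogues), all gradient-matched.
    pairs <- list()
    for (c in seq_len(n_clusters)) {
      d_idx <- which(eff_dcl == c)
      s_idx <- which(eff_cl == c)
      if (length(s_idx) == 0) next
      d_ord <- d_idx[order(eff_dt[d_idx])]
      s_ord <- s_idx[order(eff_t[s_idx])]
      n_c <- length(d_ord); m_c <- length(s_ord)
      offsets <- c(0, as.vector(rbind(seq_len(m_c), -seq_len(m_c))))
      quota <- assoc_per_cluster
      for (off in offsets) {
        if (quota <= 0) break
        take <- if (quota >= n_c) seq_len(n_c) else sort(sample.int(n_c, quota))
        for (k in take) {
          j_rank <- min(max(round((k - 0.5) / n_c * m_c + 0.5) + off, 1L), m_c)
          key <- paste(d_ord[k], s_ord[j_rank])
          if (is.null(pairs[[key]])) {
            pairs[[key]] <- data.frame(drug = drug_ids[d_ord[k]],
                                       disease = dis_ids[s_ord[j_rank]],
                                       stringsAsFactors = FALSE)
            quota <- quota - 1
          }
        }
      }
    }
    df <- do.call(rbind, pairs)
    df <- df[order(df$drug, df$disease, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  })

  cohort <- structure(list(
    smiles = smiles, targets = targets, enzymes = enzymes,
    expression = expr,
    phenotype_annotations = phenotype, genotype_annotations = genotype,
    associations = assoc,
    clusters = list(drug = stats::setNames(drug_cl, drug_ids),
                    disease = stats::setNames(dis_cl, dis_ids)),
    gradient = list(drug = stats::setNames(drug_t, drug_ids),
                    disease = stats::setNames(dis_t, dis_ids)),
    params = list(n_drugs = n_drugs, m_diseases = m_diseases,
                  n_clusters = n_clusters, assoc_per_cluster = assoc_per_cluster,
                  noise_sd = noise_sd, seed = seed,
                  shuffle_labels = shuffle_labels),
    files = NULL), class = "synthetic_cohort")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(smiles = file.path(dir, "smiles.tsv"),
              targets = file.path(dir, "targets.fasta"),
              enzymes = file.path(dir, "enzymes.fasta"),
              expression = file.path(dir, "expression.tsv"),
              expression_meta = file.path(dir, "expression_meta.tsv"),
              phenotype = file.path(dir, "phenotype.tsv"),
              genotype = file.path(dir, "genotype.tsv"),
              associations = file.path(dir, "associations.tsv"))
    writeLines(paste(names(smiles), smiles, sep = "\t"), f$smiles)
    write_grouped_fasta <- function(seq_map, path) {
      recs <- unlist(lapply(names(seq_map), function(d) {
        s <- seq_map[[d]]
        as.vector(rbind(sprintf(">%s|S%d", d, seq_along(s)), s))
      }))
      writeLines(recs, path)
    }
    write_grouped_fasta(targets, f$targets)
    write_grouped_fasta(enzymes, f$enzymes)
    write_expression_table(expr, f$expression, f$expression_meta)
    write_term_annotations(phenotype, f$phenotype)
    write_term_annotations(genotype, f$genotype)
    write_associations(assoc, f$associations)
    cohort$files <- f
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("synthetic_cohort: %d drugs x %d diseases, %d clusters, ",
                     "%d associations, noise_sd %g, seed %d%s\n"),
              p$n_drugs, p$m_diseases, p$n_clusters, nrow(x$associations),
              p$noise_sd, p$seed,
              if (isTRUE(p$shuffle_labels)) " (labels shuffled)" else ""))
  invisible(x)
}

#' Generate a low-rank expression table
#'
#' Values are \code{U \%*\% V} plus Gaussian noise, with seeded Gaussian
#' factors: one column of \code{V} per condition (a CONTROL condition
#' plus \code{n_conditions} drugs), each replicated
#' \code{n_samples_per_condition} times with independent noise. Values
#' are on the log2 scale (the table is flagged as logged).
#'
#' @param n_genes number of genes
#' @param n_samples_per_condition replicates per condition
#' @param rank planted rank (<= min of genes and total samples)
#' @param noise_sd replicate noise standard deviation
#' @param seed integer seed
#' @param n_conditions number of drug conditions (default 20)
#' @return an \code{\link{expression_table}}
#' @export
generate_lowrank_expression <- function(n_genes = 100L, n_samples_per_condition = 2L,
                                        rank = 3L, noise_sd = 0.01, seed = 1L,
                                        n_conditions = 20L) {
  n_cond <- n_conditions + 1L   # + CONTROL
  abort_if(rank > min(n_genes, n_cond * n_samples_per_condition),
           "rank %d infeasible for %d genes x %d samples",
           rank, n_genes, n_cond * n_samples_per_condition)
  with_seed(derive_seed(seed, "lowrank"), {
    U <- matrix(stats::rnorm(n_genes * rank), n_genes, rank)
    V <- matrix(stats::rnorm(rank * n_cond), rank, n_cond)
    cond_ids <- c("CONTROL", sprintf("DR%03d", seq_len(n_conditions)))
    cols <- list(); meta <- list()
    for (ci in seq_len(n_cond)) {
      for (r in seq_len(n_samples_per_condition)) {
        sid <- sprintf("%s_%d", cond_ids[ci], r)
        cols[[sid]] <- as.numeric(U %*% V[, ci]) + stats::rnorm(n_genes, sd = noise_sd)
        meta[[sid]] <- data.frame(sample_id = sid, drug_id = cond_ids[ci],
                                  cell_line = "CL1", replicate = r)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- sprintf("G%04d", seq_len(n_genes))
    expression_table(vals, do.call(rbind, meta), logged = TRUE)
  })
}

#' Generate random amino-acid sequences
#'
#' Uniform i.i.d. residues; record names follow the
#' \code{drug_id|sequence_id} grouped-FASTA dialect so the output
#' round-trips through \code{\link{read_grouped_fasta}}.
#'
#' @param n number of sequences
#' @param length_range min/max sequence length (both >= 3)
#' @param alphabet residue alphabet
#' @param seed integer seed
#' @param path optional FASTA output path
#' @return named character vector of sequences (names
#'   \code{Dk|Sk}); written to \code{path} when given
#' @export
generate_random_sequences <- function(n, length_range = c(50L, 120L),
                                      alphabet = aa_alphabet(include_x = FALSE),
                                      seed = 1L, path = NULL) {
  abort_if(min(length_range) < 3, "sequence lengths must be >= 3")
  seqs <- with_seed(derive_seed(seed, "random-seqs"), {
    rng <- seq.int(length_range[1], length_range[2])
    lens <- rng[sample.int(length(rng), n, replace = TRUE)]
    vapply(lens, function(L) paste(sample(alphabet, L, replace = TRUE),
                                   collapse = ""), character(1))
  })
  names(seqs) <- sprintf("D%d|S%d", seq_len(n), seq_len(n))
  if (!is.null(path)) {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  }
  seqs
}
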