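#' Run the full network-to-immunoscore pipeline
#'
#' Executes the sequential stages of the guilt-by-association analysis:
#' (a) random-walk association scores from the seed set, (b) optional GSEA
#' association/deregulation with truncated-product combination, (c) immune
#' correlation and immune-positive/negative selection, (d) rank-product MIAS
#' signature, (e) per-sample MIAS scores and, when response labels are
#' present, evaluation (AUC and one-sided Wilcoxon-Mann-Whitney). Stages
#' whose inputs are absent are skipped with a notice. Every run writes
#' per-stage TSVs and a JSON manifest of parameters and input checksums.
#'
#' @param config Named list, or path to a YAML file, with input paths:
#'   \code{network}, \code{seeds} (required); \code{expression},
#'   \code{immune}, \code{gene_sets}, \code{labels}, \code{cnv},
#'   \code{mutations}, \code{drugs} (optional); and parameters
#'   \code{gamma} (0.5), \code{tol} (1e-10), \code{tau} (0.01),
#'   \code{top_fraction} (0.1), \code{corr_threshold} (0.2),
#'   \code{n_signature} (100), \code{n_perm} (1000), \code{rng_seed} (1),
#'   \code{expression_unit} ("normalized").
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(gamma = 0.5, tol = 1e-10, tau = 0.01,
                   top_fraction = 0.1, corr_threshold = 0.2,
                   n_signature = 100L, n_perm = 1000L, rng_seed = 1L,
                   expression_unit = "normalized",
                   correlation_method = "spearman")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("network", "seeds")) {
    if (is.null(config[[nm]])) stop(sprintf("config missing '%s'", nm))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # (a) association
  results$association <- stage("associate", {
    net <- read_edge_list(config$network)
    seeds <- read_seeds(config$seeds)
    W <- column_normalize(net)
    rwr <- random_walk_with_restart(W, seeds, gamma = config$gamma,
                                    tol = config$tol)
    ranked <- rank_and_percentile(rwr)
    write_tsv(ranked, file.path(out_dir, "association.tsv"))
    ranked
  })

  # (b) pathway association (optional)
  if (!is.null(config$gene_sets)) {
    results$gsea <- stage("gsea", {
      sets <- read_gmt(config$gene_sets)
      assoc <- gsea_association(results$association, sets,
                                n_perm = config$n_perm,
                                rng_seed = config$rng_seed)
      out <- assoc
      if (!is.null(config$expression) && !is.null(config$labels)) {
        expr <- read_matrix(config$expression,
                            unit = config$expression_unit)
        labels <- read_labels(config$labels)
        shared <- intersect(colnames(expr), labels$sample)
        grp <- labels$response[match(shared, labels$sample)] == "response"
        dereg <- gsea_deregulation(expr[, shared, drop = FALSE], grp, sets,
                                   n_perm = config$n_perm,
                                   rng_seed = config$rng_seed)
        merged <- merge(assoc, dereg, by = "set",
                        suffixes = c("_assoc", "_dereg"))
        comb <- truncated_product(merged$p_assoc, merged$p_dereg,
                                  tau = config$tau)
        merged$w <- comb$w
        merged$p_combined <- comb$p_combined
        out <- merged
      }
      write_tsv(out, file.path(out_dir, "pathways.tsv"))
      out
    })
  }

  if (is.null(config$expression) || is.null(config$immune)) {
    message("run_pipeline: no expression/immune input; selection, signature, MIAS and evaluation skipped")
  } else {
    # (c) immune correlation and selection
    results$selection <- stage("select", {
      expr <- read_matrix(config$expression, unit = config$expression_unit)
      immune <- read_sample_scores(config$immune)
      corr <- immune_correlation(expr, immune,
                                 method = config$correlation_method)
      results$correlation <- corr
      write_tsv(corr, file.path(out_dir, "immune_correlation.tsv"))
      sel <- select_immune_genes(results$association, corr,
                                 top_fraction = config$top_fraction,
                                 corr_threshold = config$corr_threshold)
      writeLines(sel$positive, file.path(out_dir, "immune_positive.txt"))
      writeLines(sel$negative, file.path(out_dir, "immune_negative.txt"))
      sel
    })

    # (d) rank-product signature
    results$signature <- stage("signature", {
      sig <- select_mias_signature(results$association,
                                   results$correlation,
                                   n_signature = config$n_signature)
      write_tsv(sig, file.path(out_dir, "mias_signature.tsv"))
      sig
    })

    # (e) MIAS scores and evaluation
    results$mias <- stage("mias", {
      expr <- read_matrix(config$expression, unit = config$expression_unit)
      mias <- mias_score(expr, results$signature)
      write_tsv(mias, file.path(out_dir, "mias_scores.tsv"))
      mias
    })
    if (!is.null(config$labels)) {
      results$evaluation <- stage("evaluate", {
        labels <- read_labels(config$labels)
        m <- merge(results$mias, labels, by = "sample")
        is_resp <- m$response == "response"
        roc <- roc_auc(m$mias, is_resp)
        mw <- mann_whitney_one_sided(m$mias[is_resp], m$mias[!is_resp])
        ev <- data.frame(metric = c("auc", "wilcoxon_u", "wilcoxon_p"),
                         value = c(roc$auc, mw$u, mw$p))
        write_tsv(ev, file.path(out_dir, "evaluation.tsv"))
        write_tsv(roc$points, file.path(out_dir, "roc_points.tsv"))
        list(roc = roc, wilcoxon = mw)
      })
    }
    # alterations / drug mapping (optional)
    if (!is.null(config$cnv) || !is.null(config$mutations)) {
      results$alterations <- stage("alterations", {
        states <- if (!is.null(config$cnv)) {
          call_cnv_states(read_matrix(config$cnv))
        } else NULL
        muts <- if (!is.null(config$mutations)) {
          utils::read.delim(config$mutations, sep = "\t",
                            comment.char = "#", quote = "",
                            stringsAsFactors = FALSE)
        } else NULL
        alt <- recurrent_alterations(results$selection, muts, states)
        write_tsv(alt, file.path(out_dir, "alterations.tsv"))
        alt
      })
    }
    if (!is.null(config$drugs)) {
      results$drugs <- stage("drugs", {
        dt <- utils::read.delim(config$drugs, sep = "\t",
                                comment.char = "#", quote = "",
                                stringsAsFactors = FALSE)
        colnames(dt)[1:2] <- c("drug", "target")
        dg <- map_drug_targets(results$selection, dt,
                               assoc = results$association,
                               corr = results$correlation)
        write_tsv(dg, file.path(out_dir, "drug_targets.tsv"))
        dg
      })
    }
  }

  input_keys <- c("network", "seeds", "expression", "immune", "gene_sets",
                  "labels", "cnv", "mutations", "drugs")
  inputs <- unlist(config[intersect(input_keys, names(config))])
  params <- config[setdiff(names(config), input_keys)]
  write_manifest(file.path(out_dir, "manifest.json"), "run",
                 params = params, inputs = inputs)
  invisible(results)
}
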