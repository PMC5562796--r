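# End-to-end orchestration: configuration (list or YAML), stage execution,
# deterministic outputs, and a machine-readable run manifest.

default_thresholds <- function() {
  list(fc = 2, p = 0.05, use_fdr = FALSE,
       shift = list(low = -0.25, high = 0.25,
                    correlated = 0.5, anticorrelated = -0.5),
       k = 3, top_fraction = 0.02, q = 0.25, n_random = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the bulk branch (differential expression with pair-scenario
#' classification, per-condition pair correlations with summaries and K-S
#' comparison, optional random-pair null, shift classification, optional
#' infiltration stratification) and/or the single-cell branch (profiles,
#' high-expression calls, directed network, edge counts, exclusiveness
#' ranking, GraphML export) as configured, writing TSV/JSON/GraphML outputs
#' plus a `manifest.json` that records inputs, seed, thresholds, package
#' version and every file written. Reruns with the same configuration and
#' seed reproduce identical primary outputs.
#'
#' The configuration is a nested list (or path to a YAML file with the same
#' structure):
#'
#' * `pairs`: path to the ligand-receptor TSV (`pairs_header` flags a header
#'   line).
#' * `seed`: integer; mandatory whenever a stochastic stage (simulation or
#'   random null) runs.
#' * `bulk`: either `expression` + `conditions` paths, or `simulate` (a list
#'   of [bulk_cohort_spec()] arguments except `seed`).
#' * `infiltration`: a fraction TSV path, or `simulate: true` (bulk branch
#'   required).
#' * `single_cell`: either `expression` (+ `genes`/`cells` for MTX) and
#'   `annotations` paths, or `simulate` (a list of [single_cell_spec()]
#'   arguments except `seed`; `cell_types` as a named list).
#' * `thresholds`: any of `fc`, `p`, `use_fdr`, `shift` (list of
#'   [shift_thresholds()] arguments), `k`, `top_fraction`, `q`, `n_random`.
#'
#' @param config List or YAML path.
#' @param output_dir Output directory (created if absent); overrides
#'   `config$output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path", call. = FALSE)
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("an output directory is required", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  sth <- do.call(shift_thresholds, th$shift)
  needs_seed <- !is.null(config$bulk$simulate) ||
    !is.null(config$single_cell$simulate) ||
    isTRUE(config$infiltration$simulate) || !is.null(th$n_random)
  if (needs_seed && is.null(config$seed))
    stop("configuration error: a 'seed' is required for stochastic stages",
         call. = FALSE)
  manifest <- list(package = "ligrec",
                   version = as.character(utils::packageVersion("ligrec")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, thresholds = th, inputs = list(),
                   stages = list(), outputs = character(0))
  emit <- function(writer, file) {
    path <- file.path(out, file)
    writer(path)
    manifest$outputs <<- c(manifest$outputs, file)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }

  if (is.null(config$pairs)) stop("configuration error: 'pairs' path is required", call. = FALSE)
  db <- stage("pairs", load_pairs(config$pairs, header = isTRUE(config$pairs_header)))
  manifest$inputs$pairs <- config$pairs
  manifest$stages$pairs <- pair_db_counts(db)

  cohort <- NULL
  if (!is.null(config$bulk)) {
    cohort <- stage("bulk_input", {
      if (!is.null(config$bulk$simulate)) {
        args <- config$bulk$simulate
        if (!is.null(args$planted_corr))
          args$planted_corr <- as.data.frame(args$planted_corr,
                                             stringsAsFactors = FALSE)
        if (!is.null(args$planted_de)) args$planted_de <- unlist(args$planted_de)
        args$seed <- config$seed
        sim <- simulate_bulk(do.call(bulk_cohort_spec, args))
        emit(function(p) write_truth(sim$truth, p), "bulk_truth.json")
        emit(function(p) write_expression_matrix(sim$cohort$expr, p),
             "bulk_expression.tsv")
        sim$cohort
      } else {
        expr <- read_expression_matrix(config$bulk$expression)
        conds <- read_conditions(config$bulk$conditions)
        bulk_cohort(expr, conds$condition[match(colnames(expr), conds$sample)])
      }
    })
    manifest$inputs$bulk <- config$bulk[setdiff(names(config$bulk), "simulate")]

    stage("de", {
      fits <- fit_linear_model(cohort)
      res <- moderate(fits)
      sel <- select_de(res, fc_threshold = th$fc, p_threshold = th$p,
                       use_fdr = th$use_fdr)
      emit(function(p) write.table(sel$table, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "de_table.tsv")
      scen <- classify_pairs(sel$up, sel$down, db)
      emit(function(p) write.table(scen, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "pair_scenarios.tsv")
      manifest$stages$de <- list(n_up = length(sel$up), n_down = length(sel$down),
                                  d0 = attr(res, "d0"))
    })

    stage("correlate", {
      rn <- pair_correlations(cohort, db, "normal")
      rc <- pair_correlations(cohort, db, "cancer")
      both <- rbind(rn, rc)
      emit(function(p) write.table(both, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "pair_correlations.tsv")
      summ <- list(normal = as.list(summarize_distribution(rn)),
                   cancer = as.list(summarize_distribution(rc)),
                   ks_normal_vs_cancer = unclass(ks_compare(rn, rc)))
      if (!is.null(th$n_random)) {
        null_n <- random_null(cohort, db, th$n_random, seed = config$seed,
                              condition = "normal")
        null_c <- random_null(cohort, db, th$n_random, seed = config$seed + 1L,
                              condition = "cancer")
        emit(function(p) write.table(rbind(null_n[, names(null_n)],
                                           null_c[, names(null_c)]),
                                     p, sep = "\t", quote = FALSE,
                                     row.names = FALSE), "random_null.tsv")
        summ$random_normal <- as.list(summarize_distribution(null_n))
        summ$random_cancer <- as.list(summarize_distribution(null_c))
        summ$ks_specific_vs_random_cancer <- unclass(ks_compare(rc, null_c))
      }
      emit(function(p) jsonlite::write_json(summ, p, auto_unbox = TRUE,
                                            digits = NA), "correlation_summary.json")
      manifest$stages$correlate <- list(n_specific = nrow(rn))
    })

    stage("shift", {
      tab <- shift_table(cohort, db, sth)
      emit(function(p) write.table(tab, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "shift_table.tsv")
      rec <- recurrence_rank(list(cohort = tab))
      for (cat in names(rec)) {
        f <- sprintf("recurrence_%s.tsv", cat)
        local({
          cat_tab <- rec[[cat]]
          emit(function(p) write.table(cat_tab, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), f)
        })
      }
      manifest$stages$shift <- as.list(table(tab$category))
    })

    if (!is.null(config$infiltration)) {
      stage("infiltrate", {
        if (isTRUE(config$infiltration$simulate)) {
          sim <- simulate_infiltration(cohort, seed = config$seed + 2L)
          tab <- sim$infiltration
          cohort <- sim$cohort
          emit(function(p) write.table(tab, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), "infiltration.tsv")
        } else {
          tab <- read.delim(config$infiltration, stringsAsFactors = FALSE)
          manifest$inputs$infiltration <- config$infiltration
        }
        ks_list <- list()
        for (ty in intersect(INFILTRATION_TYPES, names(tab))) {
          split <- quantile_split(tab, ty, q = th$q)
          cmp <- compare_infiltration_groups(cohort, db, split)
          local({
            qq <- cmp$qq
            emit(function(p) write.table(qq, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
                 sprintf("infiltration_qq_%s.tsv", ty))
          })
          ks_list[[ty]] <- unclass(cmp$ks)
        }
        emit(function(p) jsonlite::write_json(ks_list, p, auto_unbox = TRUE,
                                              digits = NA), "infiltration_ks.json")
        manifest$stages$infiltrate <- list(cell_types = names(ks_list))
      })
    } else {
      manifest$stages$infiltrate <- "skipped"
    }
  } else {
    manifest$stages$de <- manifest$stages$correlate <-
      manifest$stages$shift <- manifest$stages$infiltrate <- "skipped"
  }

  if (!is.null(config$single_cell)) {
    stage("scnet", {
      if (!is.null(config$single_cell$simulate)) {
        args <- config$single_cell$simulate
        args$cell_types <- unlist(args$cell_types)
        if (!is.null(args$planted_edges))
          args$planted_edges <- as.data.frame(args$planted_edges,
                                              stringsAsFactors = FALSE)
        args$seed <- config$seed + 3L
        sim <- simulate_single_cells(do.call(single_cell_spec, args))
        mat <- sim$counts
        ann <- sim$annotations
        emit(function(p) write_expression_matrix(mat, p), "sc_counts.tsv")
        emit(function(p) write.table(ann, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE), "sc_annotations.tsv")
      } else {
        mat <- read_expression_matrix(config$single_cell$expression,
                                      genes_path = config$single_cell$genes,
                                      cells_path = config$single_cell$cells)
        ann <- read.delim(config$single_cell$annotations,
                          stringsAsFactors = FALSE)
        manifest$inputs$single_cell <-
          config$single_cell[setdiff(names(config$single_cell), "simulate")]
      }
      prof <- type_profiles(mat, ann)
      calls <- call_high(mat, ann, k = th$k)
      edges <- build_network(calls, db)
      emit(function(p) write.table(edges, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "sc_edges.tsv")
      counts <- edge_counts(edges, types = colnames(prof$means))
      emit(function(p) write.table(data.frame(sender = rownames(counts), counts,
                                              check.names = FALSE),
                                   p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "sc_edge_counts.tsv")
      if (nrow(edges)) {
        top <- rank_edges(edges, prof, top_fraction = th$top_fraction)
        emit(function(p) write.table(top, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE), "sc_top_edges.tsv")
        emit(function(p) export_graphml(rank_edges(edges, prof, top_fraction = 1),
                                        p), "sc_network.graphml")
      }
      manifest$stages$scnet <- list(n_edges = nrow(edges), k = th$k)
    })
  } else {
    manifest$stages$scnet <- "skipped"
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$outputs <- c(manifest$outputs, "manifest.json")
  invisible(manifest)
}
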