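#' Configure the end-to-end analysis pipeline
#'
#' Bundles the per-stage parameters of the full analysis: cohort input
#' (a generator configuration per group, or a CSV path), cleaning options,
#' categorization scheme, rule-mining thresholds, SOM settings and the
#' dependence-analysis targets.
#'
#' @param generators List of [generator_config()] objects (one per group)
#'   used to simulate the cohort; ignored when `cohort_path` is given.
#' @param cohort_path Optional CSV path of an existing cohort table.
#' @param outlier_factors Factors screened by the boxplot filter; `NULL`
#'   disables the outlier stage.
#' @param scheme Categorization scheme.
#' @param mining List of mining options: `consequents` (wtCat codes,
#'   default `c(-3, -2)`), `min_confidence`, `min_len`, `max_len`,
#'   `min_support`, `prune_redundant`.
#' @param som A [som_config()], or `NULL` to skip the SOM stage.
#' @param info List with `factors` and `combos` for [dependence_report()],
#'   or `NULL` to skip.
#' @param out_dir Output directory for stage artifacts; `NULL` disables
#'   file output.
#' @param seed Global seed; per-group generator and SOM seeds are derived
#'   from it deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generators = list(generator_config(600, seed = 1L),
                                              generator_config(400,
                                                               group = "fCont",
                                                               seed = 2L)),
                            cohort_path = NULL,
                            outlier_factors = c("tfcscore", "indepscl",
                                                "irascore", "motscore",
                                                "depscore"),
                            scheme = default_scheme(),
                            mining = list(),
                            som = som_config(epochs = 100L),
                            info = list(),
                            out_dir = NULL,
                            seed = 1L) {
  mining_defaults <- list(consequents = c(-3L, -2L), min_confidence = 0.9,
                          min_len = 2L, max_len = 5L, min_support = 0.01,
                          prune_redundant = TRUE)
  mining <- utils::modifyList(mining_defaults, mining)
  if (!is.null(info)) {
    info <- utils::modifyList(list(factors = NULL, combos = list()), info)
  }
  structure(list(generators = generators, cohort_path = cohort_path,
                 outlier_factors = outlier_factors, scheme = scheme,
                 mining = mining, som = som, info = info,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage_csv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(x, file.path(out_dir, name), row.names = FALSE, na = "")
}

#' Run the full analysis pipeline
#'
#' Executes generate (or load), clean, consolidate, categorize, mine, map
#' and dependence stages for each subject group independently, collecting
#' a manifest of record counts and parameters. Identical configurations
#' (including seeds) reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: per-group stage outputs
#'   (`cohort`, `records`, `kb`, `rules` per consequent, `som`, `info`)
#'   and `manifest`, the per-stage record accounting.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  if (!is.null(config$cohort_path)) {
    cohort <- read_cohort(config$cohort_path)
  } else {
    cohort <- do.call(rbind, lapply(config$generators, generate_cohort))
  }
  groups <- unique(cohort$group)
  result <- list()
  manifest <- list(seed = config$seed, groups = groups)
  for (g in groups) {
    tab <- cohort[cohort$group == g, , drop = FALSE]
    res <- list(cohort = tab)
    rec <- preprocess_cohort(tab, outlier_factors = config$outlier_factors)
    counts <- attr(rec, "counts")
    res$records <- rec
    kb <- categorize(rec, config$scheme)
    res$kb <- kb
    write_stage_csv(kb, config$out_dir, paste0("kb_", g, ".csv"))

    rules <- list()
    for (wc in config$mining$consequents) {
      consequent <- item_string("wtCat", wc)
      r <- mine_class_rules(kb, consequent,
                            min_confidence = config$mining$min_confidence,
                            min_len = config$mining$min_len,
                            max_len = config$mining$max_len,
                            min_support = config$mining$min_support)
      n_before <- nrow(r)
      if (isTRUE(config$mining$prune_redundant)) r <- eliminate_redundant(r)
      counts[paste0("rules_wtCat", wc, "_mined")] <- n_before
      counts[paste0("rules_wtCat", wc, "_kept")] <- nrow(r)
      rules[[consequent]] <- r
      if (!is.null(config$out_dir)) {
        export_rule_report(r, file.path(config$out_dir,
                                        sprintf("rules_%s_wtCat%d.csv", g, wc)))
        export_histogram_report(r, file.path(
          config$out_dir, sprintf("antecedent_hist_%s_wtCat%d.csv", g, wc)))
      }
    }
    res$rules <- rules

    if (!is.null(config$som)) {
      som_cfg <- config$som
      som_cfg$seed <- config$seed + match(g, groups)
      res$som <- train_som(kb, som_cfg)
      if (!is.null(config$out_dir)) {
        write_stage_csv(codes_profile(res$som), config$out_dir,
                        paste0("som_codes_", g, ".csv"))
        write_stage_csv(node_counts(res$som, kb), config$out_dir,
                        paste0("som_counts_", g, ".csv"))
        write_stage_csv(node_class_distribution(res$som, kb), config$out_dir,
                        paste0("som_wtcat_", g, ".csv"))
      }
    }
    if (!is.null(config$info)) {
      factors <- config$info$factors %||% intersect(hd_factors, names(kb))
      res$info <- dependence_report(kb, factors = factors,
                                    combos = config$info$combos)
      write_stage_csv(res$info, config$out_dir, paste0("dependence_", g, ".csv"))
    }
    result[[g]] <- res
    manifest[[g]] <- counts
  }
  structure(c(result, list(manifest = manifest)), class = "pipeline_result")
}

#' Export a rule table report
#'
#' Writes mined class rules with all six measures as CSV or JSON, plus a
#' summary line (min/max of every measure over the rule set). Non-finite
#' conviction/strength values are serialized as the token `"inf"`.
#'
#' @param rules A `class_rules` data frame.
#' @param path Output file.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return The path, invisibly.
#' @export
export_rule_report <- function(rules, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!format %in% c("csv", "json")) stop("unknown format: ", format)
  df <- as.data.frame(rules)[setdiff(names(rules), "antecedent_items")]
  num <- c("support", "confidence", "lift", "conviction", "chi2", "p_value",
           "strength")
  if (format == "csv") {
    out <- df
    for (m in c("conviction", "strength")) {
      out[[m]] <- ifelse(is.infinite(out[[m]]), "inf",
                         format(out[[m]], digits = 12, trim = TRUE))
    }
    utils::write.csv(out, path, row.names = FALSE)
    if (nrow(df)) {
      rng <- vapply(num, function(m) range(df[[m]]), numeric(2))
      summary_line <- paste0("# summary ",
        paste(sprintf("%s=[%s,%s]", num,
                      signif(rng[1, ], 6), signif(rng[2, ], 6)),
              collapse = " "))
      cat(summary_line, "\n", file = path, append = TRUE, sep = "")
    }
  } else {
    payload <- list(
      rules = lapply(seq_len(nrow(df)), function(i) {
        r <- as.list(df[i, ])
        r$antecedent_items <- rules$antecedent_items[[i]]
        r$conviction <- if (is.infinite(r$conviction)) "inf" else r$conviction
        r$strength <- if (is.infinite(r$strength)) "inf" else r$strength
        r
      }),
      summary = if (nrow(df)) {
        stats::setNames(lapply(num, function(m) {
          r <- range(df[[m]])
          list(min = if (is.infinite(r[1])) "inf" else r[1],
               max = if (is.infinite(r[2])) "inf" else r[2])
        }), num)
      } else NULL
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read back a JSON rule report
#'
#' @param path JSON file written by [export_rule_report()].
#' @return A `class_rules` data frame.
#' @export
read_rule_report <- function(path) {
  payload <- jsonlite::read_json(path)
  rules <- payload$rules
  to_num <- function(v) if (identical(v, "inf")) Inf else as.numeric(v)
  antecedents <- lapply(rules, function(r) unlist(r$antecedent_items))
  metrics <- lapply(rules, function(r) {
    list(support_count = as.integer(r$support_count), support = r$support,
         confidence = r$confidence, lift = to_num(r$lift),
         conviction = to_num(r$conviction), chi2 = r$chi2,
         p_value = r$p_value, strength = to_num(r$strength))
  })
  cons <- vapply(rules, function(r) r$consequent, "")
  make_rules_df(antecedents, cons, metrics)
}

#' Export the antecedent histogram of a rule set
#'
#' Tidy per-item counts (`factor`, `category`, `count`) across all rule
#' antecedents; an empty rule set yields a header-only file.
#'
#' @param rules A `class_rules` data frame.
#' @param path Output CSV file.
#' @return The path, invisibly.
#' @export
export_histogram_report <- function(rules, path) {
  hist <- antecedent_histogram(rules)
  utils::write.csv(hist[c("factor", "category", "count")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result for group(s):",
      paste(x$manifest$groups, collapse = ", "), "\n")
  for (g in x$manifest$groups) {
    cat("\n[", g, "]\n", sep = "")
    print(x$manifest[[g]])
  }
  invisible(x)
}
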