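#' Build an analysis configuration
#'
#' Collects everything the pipeline drivers need: the inputs (as in-memory
#' objects or file paths), the permutation count, the master seed, the
#' lambda mode, the optionally excluded site, and per-trait transforms.
#'
#' @param seed master integer seed (mandatory; every stage derives its own
#'   stream from it).
#' @param tree a `"phylo"` object, or `NULL` to read/assemble from files.
#' @param table a trait table data frame, or `NULL` to read from
#'   `traits_file`.
#' @param tree_file Newick file: the analysis tree, or (with `taxa_file`)
#'   the family-level backbone.
#' @param taxa_file,ages_file taxon-list CSV and node-age file for tree
#'   assembly; `taxa_file` without `ages_file` is an error (undated trees
#'   are not analyzed).
#' @param traits_file species-site trait CSV (see [read_trait_table()]).
#' @param out_dir directory for TSV reports and the run log (`NULL` = do
#'   not write).
#' @param n_perm tip shuffles per signal test (default 999).
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @param exclude_site site id for the with/without-site signal contrast;
#'   `"hottest"` (default) picks the warmest site in the table.
#' @param transforms named character vector overriding the default
#'   transform (`log10` for everything except margin codes).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(seed, tree = NULL, table = NULL,
                            tree_file = NULL, taxa_file = NULL,
                            ages_file = NULL, traits_file = NULL,
                            out_dir = NULL, n_perm = 999L, lambda = "ML",
                            exclude_site = "hottest", transforms = NULL) {
  if (missing(seed)) stopf("'seed' is required")
  for (f in c(tree_file, taxa_file, ages_file, traits_file))
    if (!is.null(f) && !file.exists(f)) stopf("input file not found: %s", f)
  if (!is.null(taxa_file) && is.null(ages_file))
    stopf("a taxon file requires an ages file: undated trees are not analyzed")
  structure(list(seed = seed, tree = tree, table = table,
                 tree_file = tree_file, taxa_file = taxa_file,
                 ages_file = ages_file, traits_file = traits_file,
                 out_dir = out_dir, n_perm = as.integer(n_perm),
                 lambda = lambda, exclude_site = exclude_site,
                 transforms = transforms),
            class = "analysis_config")
}

#' @keywords internal
resolve_inputs <- function(config) {
  tab <- config$table %||% read_trait_table(config$traits_file %||%
                                              stopf("no trait table given"))
  tree <- config$tree
  if (is.null(tree)) {
    if (is.null(config$tree_file)) stopf("no tree given")
    tree <- read_newick(file = config$tree_file)
    if (!is.null(config$taxa_file)) {
      taxa <- read_taxa(config$taxa_file)
      ages <- read_ages(config$ages_file)
      tree <- smooth_ages(graft_taxa(tree, taxa), ages)
    }
  }
  miss <- setdiff(rownames(tab), tree$tip.label)
  if (length(miss))
    stopf("trait-table labels missing from tree: %s%s",
          paste(head(miss, 5L), collapse = ", "),
          if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  ex <- config$exclude_site
  if (identical(ex, "hottest"))
    ex <- tab$site[which.max(tab$mat)][1L]
  list(tree = tree, table = tab, exclude_site = ex)
}

#' @keywords internal
trait_columns <- function(table) {
  meta <- c("label", "family", "genus", "species", "site", "mat",
            "margin_binomial")
  setdiff(names(table), meta)
}

#' @keywords internal
transform_for <- function(trait, transforms) {
  if (!is.null(transforms) && trait %in% names(transforms))
    return(transforms[[trait]])
  if (is_margin_trait(trait) || trait == "margin_ternary") "none" else "log10"
}

#' Per-trait phylogenetic-signal report
#'
#' One row per trait (MAT first, then the margin code, then the remaining
#' trait columns): Blomberg's K, sample size and tip-shuffle P-value on
#' all data, and again with the excluded site removed.  Traits are pruned
#' per trait for missing values, so N varies across rows.
#'
#' @param config an [analysis_config()].
#' @return data frame with columns `trait`, `k_all`, `n_all`, `p_all`,
#'   `k_excl`, `n_excl`, `p_excl`.
#' @export
run_signal_table <- function(config) {
  inp <- resolve_inputs(config)
  tab <- inp$table
  tab_ex <- exclude_site(tab, inp$exclude_site)
  traits <- c("mat", intersect("margin_ternary", names(tab)),
              setdiff(trait_columns(tab), c("mat", "margin_ternary")))
  rows <- lapply(seq_along(traits), function(i) {
    tr_name <- traits[i]
    one <- function(t, stream) {
      prep <- prepare_trait(t, tr_name, transform_for(tr_name, config$transforms))
      if (var(prep$values) == 0) {
        warnf("trait '%s' has zero variance in this subset; signal undefined",
              tr_name)
        return(c(K = NA_real_, N = prep$n, P = NA_real_))
      }
      st <- signal_test(inp$tree, prep$values, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, stream),
                        trait_name = tr_name)
      c(K = st$K, N = st$n, P = st$P)
    }
    all <- one(tab, i)
    exc <- one(tab_ex, 1000L + i)
    data.frame(trait = tr_name, k_all = all["K"], n_all = all["N"],
               p_all = all["P"], k_excl = exc["K"], n_excl = exc["N"],
               p_excl = exc["P"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  maybe_write(out, config, "signal_table.tsv")
  out
}

#' Per-trait GLS versus phylogenetic-GLS report
#'
#' For each trait (margin code included as a continuous ternary response,
#' plus a flagged binomial PQL row), fits the non-phylogenetic GLS and the
#' lambda-scaled phylogenetic GLS of the (log10) trait on log10 MAT and
#' reports intercepts, slopes, their standard errors, lambda and AIC.
#'
#' @param config an [analysis_config()].
#' @return data frame with columns `trait`, `model`, `n`, `intercept`,
#'   `se_intercept`, `slope`, `se_slope`, `lambda`, `aic`.
#' @export
run_regression_table <- function(config) {
  inp <- resolve_inputs(config)
  tab <- inp$table
  traits <- c(intersect("margin_ternary", names(tab)),
              setdiff(trait_columns(tab), c("mat", "margin_ternary")))
  res_row <- function(trait, model, fit) {
    cf <- coef(fit)
    data.frame(trait = trait, model = model, n = fit$n,
               intercept = cf[1L], se_intercept = fit$se[1L],
               slope = cf[2L], se_slope = fit$se[2L],
               lambda = if (fit$kind == "pgls") fit$lambda else NA_real_,
               aic = fit$aic, row.names = NULL)
  }
  rows <- list()
  for (tr_name in traits) {
    prep <- prepare_trait(tab, tr_name, transform_for(tr_name, config$transforms))
    d <- data.frame(y = unname(prep$values),
                    x = log10(tab[prep$labels, "mat"]),
                    row.names = prep$labels)
    g <- fit_gls(y ~ x, d)
    p <- fit_pgls(y ~ x, d, inp$tree, lambda = config$lambda)
    rows[[length(rows) + 1L]] <- res_row(tr_name, "gls", g)
    rows[[length(rows) + 1L]] <- res_row(tr_name, "pgls", p)
  }
  if ("margin_binomial" %in% names(tab)) {
    d <- data.frame(y = tab$margin_binomial, x = log10(tab$mat),
                    row.names = rownames(tab))
    b <- fit_binomial_pql(y ~ x, d, inp$tree)
    rows[[length(rows) + 1L]] <- res_row("margin_binomial", "binomial-pql", b)
  }
  out <- do.call(rbind, rows)
  maybe_write(out, config, "regression_table.tsv")
  out
}

#' @keywords internal
maybe_write <- function(df, config, file) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(format(df, digits = 10, trim = TRUE),
              file.path(config$out_dir, file),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Assembles/dates the tree if a taxon and ages file are given, prepares
#' the trait table, and produces the signal and regression reports plus a
#' plain-text run log (seed, input digests, per-trait sample sizes).
#'
#' @param config an [analysis_config()].
#' @return list with `signal`, `regression`, `tree`, `excluded_site`,
#'   and `log` (character vector of log lines).
#' @export
end_to_end <- function(config) {
  inp <- resolve_inputs(config)
  cfg2 <- config
  cfg2$tree <- inp$tree
  cfg2$table <- inp$table
  sig <- run_signal_table(cfg2)
  reg <- run_regression_table(cfg2)
  log <- c(sprintf("leafphylo %s", as.character(utils::packageVersion("leafphylo"))),
           sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("seed: %s", format(config$seed)),
           sprintf("n_perm: %d", config$n_perm),
           sprintf("lambda mode: %s", paste(config$lambda, collapse = "")),
           sprintf("tips: %d  rows: %d  sites: %d", ape::Ntip(inp$tree),
                   nrow(inp$table), length(unique(inp$table$site))),
           sprintf("excluded site: %s", inp$exclude_site),
           sprintf("per-trait N: %s",
                   paste(sprintf("%s=%d", sig$trait, sig$n_all), collapse = ", ")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  list(signal = sig, regression = reg, tree = inp$tree,
       excluded_site = inp$exclude_site, log = log)
}
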