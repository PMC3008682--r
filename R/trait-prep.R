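#' Code leaf-margin state from specimen observations
#'
#' A species-site record is summarized from its specimens' margin states:
#' the ternary code is 1 when all leaves are untoothed, 0.5 when both
#' toothed and untoothed specimens occur, and 0 when toothed; the binomial
#' code is 1 only when all specimens are untoothed (any toothed specimen
#' gives 0).
#'
#' @param specimen_states character vector with elements `"toothed"` or
#'   `"untoothed"` (one per specimen).
#' @return named numeric vector `c(ternary = ..., binomial = ...)`.
#' @examples
#' code_margin(c("toothed", "untoothed"))  # c(0.5, 0)
#' @export
code_margin <- function(specimen_states) {
  if (length(specimen_states) == 0L) stopf("empty specimen list")
  bad <- setdiff(unique(specimen_states), c("toothed", "untoothed"))
  if (length(bad)) stopf("unknown margin states: %s", paste(bad, collapse = ", "))
  any_toothed <- any(specimen_states == "toothed")
  any_untoothed <- any(specimen_states == "untoothed")
  ternary <- if (!any_toothed) 1 else if (any_untoothed) 0.5 else 0
  c(ternary = ternary, binomial = as.numeric(!any_toothed))
}

#' Read a species-site trait table
#'
#' CSV (UTF-8, header row) with taxonomy columns `family,genus,species,site`,
#' a `mat` column (mean annual temperature, degrees C) and any number of
#' trait columns.  Row labels are `Genus_species@site`.
#'
#' @param file path to the CSV.
#' @return data frame with a `label` column and row names set to it.
#' @export
read_trait_table <- function(file) {
  tab <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- trimws(names(tab))
  tab <- validate_taxa(tab)
  if (!"mat" %in% names(tab)) stopf("trait table lacks a 'mat' column")
  if (any(!is.finite(tab$mat))) stopf("non-finite MAT values")
  rownames(tab) <- tab$label
  tab
}

is_margin_trait <- function(trait) grepl("^margin", trimws(tolower(trait)))

#' Extract and transform one trait column
#'
#' Returns the finite values of a trait keyed by tip label, optionally
#' log10-transformed.  Rows with missing values are dropped (tooth traits
#' exist only where teeth do, so per-trait sample sizes differ), and
#' non-positive values under a log10 transform are dropped with a warning.
#' Margin codes are categorical/proportional, so requesting log10 for a
#' margin trait is refused.
#'
#' @param table trait table (see [read_trait_table()]).
#' @param trait trait column name (matched exactly after whitespace
#'   trimming).
#' @param transform `"none"` or `"log10"`.
#' @return list with `labels`, `values`, `n`, `n_dropped_missing`,
#'   `n_dropped_nonpositive`.
#' @export
prepare_trait <- function(table, trait, transform = c("none", "log10")) {
  transform <- match.arg(transform)
  trait <- trimws(trait)
  names(table) <- trimws(names(table))
  if (!trait %in% names(table)) stopf("no trait column '%s'", trait)
  if (transform == "log10" && is_margin_trait(trait))
    stopf("margin codes are not log-transformable; use transform = \"none\"")
  labels <- if ("label" %in% names(table)) as.character(table$label) else rownames(table)
  v <- suppressWarnings(as.numeric(table[[trait]]))
  keep <- is.finite(v)
  n_missing <- sum(!keep)
  n_nonpos <- 0L
  if (transform == "log10") {
    pos <- keep & v > 0
    n_nonpos <- sum(keep & !pos)
    if (n_nonpos > 0L)
      warnf("dropped %d non-positive values of '%s' before log10", n_nonpos, trait)
    keep <- pos
  }
  if (!any(keep)) stopf("no usable rows for trait '%s'", trait)
  v <- v[keep]
  if (transform == "log10") v <- log10(v)
  list(labels = labels[keep], values = setNames(v, labels[keep]),
       n = sum(keep), n_dropped_missing = n_missing,
       n_dropped_nonpositive = n_nonpos)
}

#' Remove one site from a trait table
#'
#' @param table trait table with a `site` column.
#' @param site site id to remove (must exist).
#' @return the table without that site's rows; pruning any tree is left to
#'   the caller.
#' @export
exclude_site <- function(table, site) {
  if (!"site" %in% names(table)) stopf("table lacks a 'site' column")
  if (!site %in% table$site) stopf("unknown site '%s'", site)
  table[table$site != site, , drop = FALSE]
}

#' Per-site proportion of untoothed species and site MAT
#'
#' The classical leaf-margin-analysis summary: for each site, NT is the
#' mean of the ternary margin codes over its species (untoothed = 1, mixed
#' = 0.5, toothed = 0), reported next to the site's mean annual
#' temperature.
#'
#' @param table trait table with `site`, `mat` and `margin_ternary` columns.
#' @return data frame with columns `site`, `nt`, `mat`, `n_species`.
#' @export
site_nt_proportion <- function(table) {
  need <- c("site", "mat", "margin_ternary")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("table lacks columns: %s", paste(miss, collapse = ", "))
  ok <- is.finite(table$margin_ternary)
  tab <- table[ok, , drop = FALSE]
  empty <- setdiff(unique(table$site), unique(tab$site))
  if (length(empty))
    warnf("sites with no coded species excluded: %s", paste(empty, collapse = ", "))
  agg <- aggregate(tab$margin_ternary, by = list(site = tab$site), FUN = mean)
  mats <- aggregate(tab$mat, by = list(site = tab$site), FUN = mean)
  ns <- aggregate(rep(1L, nrow(tab)), by = list(site = tab$site), FUN = sum)
  out <- data.frame(site = agg$site, nt = agg$x, mat = mats$x, n_species = ns$x)
  out[order(out$mat), , drop = FALSE]
}
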