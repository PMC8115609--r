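#' Abundance table container
#'
#' A light container for a features x samples relative-abundance matrix, in
#' the spirit of limma's list-based objects. `feature_kind` distinguishes
#' taxon tables (MetaPhlAn-style clade rows, values in percent) from pathway
#' tables (HUMAnN-style rows). For taxon tables each feature carries its
#' taxonomic level, derived from the number of rank prefixes in the clade
#' string (`k__...|p__...|...|s__...`).
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames); non-negative relative abundances.
#' @param feature_kind `"taxon"` or `"pathway"`.
#' @return an object of class `abund_table` (a list with elements `values`,
#'   `feature_kind`, and for taxon tables `taxon_level`, a named character
#'   vector per feature).
#' @export
abund_table <- function(values, feature_kind = c("taxon", "pathway")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(values < 0)) stop("negative abundances")
  out <- list(values = values, feature_kind = feature_kind)
  if (feature_kind == "taxon") {
    out$taxon_level <- vapply(rownames(values), clade_level, character(1))
  }
  structure(out, class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("abund_table [%s]: %d features x %d samples\n",
              x$feature_kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$taxon_level))
    print(table(x$taxon_level))
  invisible(x)
}

#' @export
dim.abund_table <- function(x) dim(x$values)

# Coerce an abund_table or plain matrix to the underlying matrix.
tab_values <- function(x) {
  if (inherits(x, "abund_table")) x$values
  else if (is.matrix(x)) x
  else stop("expected an abund_table or a matrix")
}

rank_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__", "t__")
rank_names <- c("kingdom", "phylum", "class", "order", "family",
                "genus", "species", "strain")

# Taxonomic level of a MetaPhlAn clade string = its deepest rank prefix.
clade_level <- function(clade) {
  parts <- strsplit(clade, "|", fixed = TRUE)[[1]]
  pref <- substr(parts, 1L, 3L)
  if (!all(pref %in% rank_prefixes) || length(parts) < 1L)
    stop("malformed clade string: ", clade)
  rank_names[match(pref[length(pref)], rank_prefixes)]
}

#' Restrict a taxon table to a single taxonomic level
#'
#' @param table an `abund_table` with `feature_kind = "taxon"`.
#' @param level one of kingdom, phylum, class, order, family, genus, species.
#' @return an `abund_table` containing only the rows at `level`.
#' @export
taxa_at_level <- function(table, level = "species") {
  stopifnot(inherits(table, "abund_table"), table$feature_kind == "taxon")
  level <- match.arg(level, rank_names)
  keep <- table$taxon_level == level
  if (!any(keep)) stop("no features at level ", level)
  abund_table(table$values[keep, , drop = FALSE], "taxon")
}

#' Display name of a clade string
#'
#' Strips the leading rank prefixes and converts underscores to spaces, so
#' `...|s__Bifidobacterium_longum` becomes `"Bifidobacterium longum"`.
#'
#' @param clade character vector of clade strings.
#' @return character vector of display names.
#' @export
taxon_display_name <- function(clade) {
  last <- vapply(strsplit(clade, "|", fixed = TRUE),
                 function(p) p[length(p)], character(1))
  gsub("_", " ", sub("^[a-z]__", "", last))
}

# Short species key (the s__ token, underscores kept) used to join abundance
# rows with haplotype alignments and ground truth.
species_key <- function(clade) {
  vapply(strsplit(clade, "|", fixed = TRUE),
         function(p) sub("^s__", "", p[length(p)]), character(1))
}

#' Prevalence/abundance feature filter
#'
#' Keeps features detected (abundance strictly greater than zero) in at least
#' `min_prevalence` of the scope samples *and* with mean relative abundance
#' strictly greater than `min_mean_abundance` over the scope samples. These
#' are the reporting filters of the sharing meta-analysis (e.g. species with
#' > 0.1% mean relative abundance and at least 5% prevalence).
#'
#' @param table `abund_table` or matrix (features x samples).
#' @param min_prevalence fraction of scope samples, in `[0, 1]`.
#' @param min_mean_abundance strict lower bound on the mean (same units as
#'   the table, i.e. percent for taxon tables).
#' @param scope_samples sample ids over which prevalence and means are
#'   computed (default: all samples).
#' @return an object of the same class restricted to the surviving features.
#' @export
filter_features <- function(table, min_prevalence = 0.05,
                            min_mean_abundance = 0.1,
                            scope_samples = NULL) {
  vals <- tab_values(table)
  if (is.null(scope_samples)) scope_samples <- colnames(vals)
  if (length(scope_samples) == 0L) stop("empty sample scope")
  if (!all(scope_samples %in% colnames(vals)))
    stop("scope_samples not all present in table")
  sc <- vals[, scope_samples, drop = FALSE]
  prev <- rowMeans(sc > 0)
  mn <- rowMeans(sc)
  keep <- prev >= min_prevalence & mn > min_mean_abundance
  out <- vals[keep, , drop = FALSE]
  if (inherits(table, "abund_table")) abund_table(out, table$feature_kind)
  else out
}
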