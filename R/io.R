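#' Read a MetaPhlAn-style merged abundance table
#'
#' Parses the merged-table dialect: tab-separated, first column clade strings
#' (`k__...|p__...|...`), remaining columns one numeric column per sample with
#' percent relative abundances. Rows may mix taxonomic levels; use
#' [taxa_at_level()] to restrict.
#'
#' @param path file path.
#' @return an [abund_table()] with `feature_kind = "taxon"`.
#' @export
read_metaphlan <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected clade column plus at least one sample")
  clades <- as.character(df[[1L]])
  for (j in 2:ncol(df)) {
    if (!is.numeric(df[[j]]))
      stop("non-numeric abundance in column '", names(df)[j], "'")
  }
  bad <- !grepl("^k__", clades)
  if (any(bad))
    stop("malformed clade string in row ", which(bad)[1L], ": ",
         clades[which(bad)[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- clades
  abund_table(m, "taxon")
}

#' Write a MetaPhlAn-style merged abundance table
#'
#' @param table `abund_table` (taxon kind) or matrix with clade rownames.
#' @param path output file path.
#' @export
write_metaphlan <- function(table, path) {
  m <- tab_values(table)
  df <- data.frame(ID = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HUMAnN-style joined pathway abundance table
#'
#' First column holds pathway ids, optionally suffixed
#' `|g__Genus.s__Genus_species` for species-stratified rows; `UNMAPPED` and
#' `UNINTEGRATED` rows are bookkeeping rows for reads outside the pathway
#' catalog.
#'
#' @param path file path.
#' @param drop_stratified drop `|`-suffixed species-stratified rows
#'   (default `TRUE`; set `FALSE` to retain only the stratified rows in a
#'   second table would be a separate call with `stratified_only = TRUE`).
#' @param stratified_only keep only the stratified rows.
#' @param drop_unmapped drop `UNMAPPED`/`UNINTEGRATED` rows before any
#'   renormalization (default `TRUE`).
#' @param renormalize rescale each sample to sum to 100 (community rows
#'   only; applied after the drops).
#' @return an [abund_table()] with `feature_kind = "pathway"`.
#' @export
read_humann_pathways <- function(path, drop_stratified = TRUE,
                                 stratified_only = FALSE,
                                 drop_unmapped = TRUE,
                                 renormalize = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ", ids[anyDuplicated(ids)])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  is_strat <- grepl("|", ids, fixed = TRUE)
  base_id <- sub("\\|.*$", "", ids)
  is_unmapped <- base_id %in% c("UNMAPPED", "UNINTEGRATED")
  keep <- if (stratified_only) is_strat else if (drop_stratified) !is_strat
          else rep(TRUE, length(ids))
  if (drop_unmapped) keep <- keep & !is_unmapped
  m <- m[keep, , drop = FALSE]
  if (renormalize) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2L, cs, "/") * 100
  }
  abund_table(m, "pathway")
}

#' Write a HUMAnN-style joined pathway table
#'
#' @param table `abund_table` (pathway kind) or matrix; rownames may include
#'   stratified and `UNMAPPED` rows.
#' @param path output file path.
#' @export
write_humann_pathways <- function(table, path) {
  m <- tab_values(table)
  df <- data.frame(m, check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(`# Pathway` = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metadata_required_cols <- c("sample_id", "subject_id", "dyad_id", "role",
                            "study_id", "day", "day_scale")

#' Read / validate a sample-metadata table
#'
#' Expects one row per sample with at least `sample_id`, `subject_id`,
#' `dyad_id`, `role` (mother/infant), `study_id`, `day`, `day_scale`
#' (gestational/postnatal), plus any clinical covariate columns
#' (`delivery_mode`, `feeding`, ...).
#'
#' @param path file path (TSV).
#' @return a validated `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_sample_metadata
#' @param metadata data.frame to validate in place of reading a file.
#' @export
validate_metadata <- function(metadata) {
  miss <- setdiff(metadata_required_cols, names(metadata))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(metadata$role %in% c("mother", "infant")))
    stop("role must be 'mother' or 'infant'")
  if (!all(metadata$day_scale %in% c("gestational", "postnatal")))
    stop("day_scale must be 'gestational' or 'postnatal'")
  if (any(metadata$day < 0)) stop("negative sampling day")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(metadata$role == "infant" & metadata$day_scale == "gestational"))
    stop("infant samples cannot be on the gestational day scale")
  metadata
}

#' Write a sample-metadata table
#' @param metadata data.frame of per-sample metadata.
#' @param path output file path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an aligned SNP-haplotype FASTA for one species
#'
#' One record per sample (record id = sample id), all sequences the same
#' length, alphabet A/C/G/T/-.
#'
#' @param path aligned FASTA file.
#' @param species species label; defaults to the file name stem (with a
#'   trailing `.aln` removed).
#' @return a `haplotype_alignment`: list with `species` and `sequences`
#'   (named uppercase character vector).
#' @export
read_haplotype_fasta <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.aln$", "", sub("\\.[^.]*$", "", basename(path)))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  haplotype_alignment(species, seqs)
}

#' Construct a haplotype alignment
#' @param species species label.
#' @param sequences named character vector of equal-length aligned sequences
#'   (names are sample ids).
#' @export
haplotype_alignment <- function(species, sequences) {
  if (length(sequences) < 1L || is.null(names(sequences)))
    stop("need at least one named sequence")
  if (anyDuplicated(names(sequences)))
    stop("one dominant-strain haplotype per sample: duplicate sample id")
  if (length(unique(nchar(sequences))) != 1L)
    stop("aligned sequences must all have the same length")
  structure(list(species = species, sequences = sequences),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %s, %d samples x %d sites\n",
              x$species, length(x$sequences), nchar(x$sequences[[1L]])))
  invisible(x)
}

#' Write an aligned haplotype FASTA
#' @param alignment a `haplotype_alignment`.
#' @param path output FASTA path.
#' @export
write_haplotype_fasta <- function(alignment, path) {
  ss <- Biostrings::BStringSet(alignment$sequences)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
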