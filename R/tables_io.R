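## Reading/writing the plain-text formats the pipeline touches: taxon count
## tables (TSV, first header cell "taxon_id"), sample manifests, newick trees.
## Dialect: tab-separated, UTF-8, "#" comment lines ignored.

.SITES <- c("fecal", "salivary")
.FRACTIONS <- c("pos", "neg", "unsorted")
.GROUPS <- c("axSpA", "HC")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, fileEncoding = "UTF-8")
}

#' Read a taxon-by-sample count table
#'
#' Parses a tab-separated count table whose first header cell is literally
#' \code{taxon_id}, remaining columns one per sample. Lines starting with
#' \code{#} are ignored. All cells must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix (taxa x samples) with unique dimnames, row and
#'   column order preserved from the file.
#' @export
readCountTable <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("count table needs a taxon_id column and >= 1 sample column")
  if (colnames(df)[1] != "taxon_id")
    stop("first header cell must be 'taxon_id', got '", colnames(df)[1], "'")
  samples <- colnames(df)[-1]
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicated sample id(s) in header: ",
                        paste(unique(dup), collapse = ", "))
  taxa <- df[[1]]
  dup <- taxa[duplicated(taxa)]
  if (length(dup)) stop("duplicated taxon id(s): ", paste(unique(dup), collapse = ", "))
  m <- matrix(0L, nrow(df), length(samples), dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count at taxon '%s', sample '%s': '%s'",
                   taxa[bad[1]], samples[j], df[[j + 1]][bad[1]]))
    m[, j] <- as.integer(v)
  }
  m
}

#' Write a count table as TSV
#'
#' Inverse of [readCountTable()]; round-trips exactly.
#'
#' @param counts Integer matrix (taxa x samples) with dimnames.
#' @param path Output path.
#' @export
writeCountTable <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest links each sequenced sample to its subject, anatomical site,
#' sorted fraction and clinical group, with an optional BASDAI disease
#' activity score (0-10) and optional \code{sex}/\code{age} covariates.
#'
#' @param path Path to a TSV with required columns \code{sample_id},
#'   \code{subject_id}, \code{site} (fecal/salivary), \code{fraction}
#'   (pos/neg/unsorted), \code{group} (axSpA/HC); optional \code{basdai},
#'   \code{sex}, \code{age}. Blank \code{basdai} cells are missing values.
#' @return A validated data.frame, one row per sample.
#' @export
readManifest <- function(path) {
  df <- .read_tsv(path)
  req <- c("sample_id", "subject_id", "site", "fraction", "group")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("manifest is missing required column(s): ",
                         paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicated sample_id(s): ", paste(unique(dup), collapse = ", "))
  .check_tokens <- function(v, allowed, what) {
    bad <- setdiff(unique(v), allowed)
    if (length(bad))
      stop(sprintf("unknown %s token(s) %s; allowed: %s", what,
                   paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")))
  }
  .check_tokens(df$site, .SITES, "site")
  .check_tokens(df$fraction, .FRACTIONS, "fraction")
  .check_tokens(df$group, .GROUPS, "group")
  key <- paste(df$subject_id, df$site, df$fraction, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("more than one sample for (subject, site, fraction): ",
         paste(unique(gsub("\r", "/", dup)), collapse = ", "))
  if ("basdai" %in% colnames(df)) {
    b <- df$basdai
    b[b == "" | b == "NA"] <- NA
    b <- suppressWarnings(as.numeric(b))
    if (any(!is.na(b) & (b < 0 | b > 10)))
      stop("basdai values must lie in [0, 10]")
    df$basdai <- b
  } else df$basdai <- NA_real_
  if ("age" %in% colnames(df)) {
    a <- df$age; a[a == "" | a == "NA"] <- NA
    df$age <- suppressWarnings(as.numeric(a))
  }
  df
}

#' Write a sample manifest as TSV
#' @param manifest Data.frame as returned by [readManifest()].
#' @param path Output path.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Missing branch lengths are set to 0 with a warning. Trees with a
#' trifurcating (unrooted) root are midpoint-rooted with a warning, since
#' unweighted UniFrac is computed on the rooted form.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object, rooted, with branch lengths.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("failed to parse newick file '", path,
                                          "': ", conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("failed to parse newick file '", path, "'")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; setting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (!ape::is.rooted(tr)) {
    warning("tree is unrooted (trifurcating root); midpoint-rooting it")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Join a count table and manifest into paired fractions
#'
#' Retains subjects that have both an IgA+ (\code{pos}) and an IgA-
#' (\code{neg}) sample at the requested site and whose samples are present in
#' the count table; everything else is dropped with a message. Subjects are
#' returned in sorted order, taxa in count-table order; no count is altered.
#'
#' @param counts Integer matrix from [readCountTable()].
#' @param manifest Data.frame from [readManifest()].
#' @param site \code{"fecal"} or \code{"salivary"}.
#' @return A [PairedFractions-class] object.
#' @export
pairFractions <- function(counts, manifest, site = "fecal") {
  site <- match.arg(site, .SITES)
  mf <- manifest[manifest$site == site & manifest$fraction %in% c("pos", "neg"), ,
                 drop = FALSE]
  mf <- mf[mf$sample_id %in% colnames(counts), , drop = FALSE]
  have <- split(mf$fraction, mf$subject_id)
  complete <- sort(names(have)[vapply(have, function(f)
    all(c("pos", "neg") %in% f), logical(1))])
  dropped <- setdiff(unique(manifest$subject_id[manifest$site == site]), complete)
  if (length(dropped))
    message("pairFractions: dropped subject(s) without a complete ", site,
            " pos/neg pair: ", paste(sort(dropped), collapse = ", "))
  if (!length(complete))
    stop("no subject has both pos and neg fractions at site '", site, "'")
  sample_of <- function(frac) vapply(complete, function(s)
    mf$sample_id[mf$subject_id == s & mf$fraction == frac], character(1))
  pos <- counts[, sample_of("pos"), drop = FALSE]
  neg <- counts[, sample_of("neg"), drop = FALSE]
  colnames(pos) <- colnames(neg) <- complete
  first_row <- mf[match(complete, mf$subject_id), , drop = FALSE]
  cd <- DataFrame(subject_id = complete, group = first_row$group,
                  site = site, basdai = first_row$basdai)
  for (col in c("sex", "age"))
    if (col %in% colnames(mf)) cd[[col]] <- first_row[[col]]
  PairedFractions(pos, neg, cd)
}
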