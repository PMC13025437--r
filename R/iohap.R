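# ---- alignment I/O ---------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Reads an alignment of equal-length nucleotide sequences. Sequences are
#' returned as an \code{ape::DNAbin} matrix (rows = individuals), the
#' container all downstream statistics consume.
#'
#' @param path Path to a FASTA file.
#' @param format Input format; only \code{"fasta"} is supported.
#' @return A \code{DNAbin} matrix with one row per sequence.
#' @details Ragged alignments (sequences of unequal length) are rejected:
#'   every statistic here assumes positional homology, so an unaligned file
#'   is an input error, not something to pad silently.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("input error: file not found: ", path)
  aln <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(aln) || length(aln) == 0L) {
    stop("input error: no sequences in ", path)
  }
  lens <- lengths(aln)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: unequal sequence lengths (",
         paste(range(lens), collapse = "-"), ") in ", path)
  }
  if (anyDuplicated(names(aln))) {
    stop("input error: duplicated sequence ids in ", path)
  }
  as.matrix(aln)
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{DNAbin} matrix or named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_dnabin(aln)
  ape::write.FASTA(aln, path)
  invisible(path)
}

# Coerce character matrix / vector of strings / DNAbin to DNAbin matrix.
as_dnabin <- function(x) {
  if (inherits(x, "DNAbin")) return(as.matrix(x))
  if (is.character(x) && is.null(dim(x))) {
    x <- do.call(rbind, lapply(strsplit(x, ""), identity))
  }
  ape::as.DNAbin(x)
}

# Upper-case character matrix view of an alignment (rows = ids).
aln_chars <- function(aln) {
  if (inherits(aln, "DNAbin")) {
    m <- toupper(as.character(as.matrix(aln)))
  } else if (is.matrix(x = aln) && is.character(aln)) {
    m <- toupper(aln)
  } else if (is.character(aln)) {
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  } else {
    stop("unsupported alignment representation: ", class(aln)[1L])
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

# Columns kept under a site policy. "complete" drops any column containing
# a gap, N or other ambiguity (the DnaSP complete-deletion convention);
# "strict" keeps every column and compares full strings verbatim.
retained_columns <- function(m, site_policy = c("complete", "strict")) {
  site_policy <- match.arg(site_policy)
  if (site_policy == "strict") return(seq_len(ncol(m)))
  keep <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
  which(keep)
}

#' Collapse aligned sequences into haplotypes
#'
#' Two sequences belong to the same haplotype iff they are identical at all
#' retained sites. Labels \code{H01, H02, ...} are assigned in order of first
#' appearance so the labelling is deterministic for a given input file.
#'
#' @param aln Alignment (\code{DNAbin} matrix or character).
#' @param site_policy \code{"complete"} (drop columns containing gaps or
#'   ambiguities before comparison; default) or \code{"strict"} (compare
#'   full sequences).
#' @return A list with \code{labels} (named character vector, id ->
#'   haplotype label), \code{counts} (named integer vector per label),
#'   \code{representatives} (named character vector of full-length
#'   representative sequences, first member of each class) and
#'   \code{n_retained_sites}.
#' @export
collapse_haplotypes <- function(aln, site_policy = c("complete", "strict")) {
  site_policy <- match.arg(site_policy)
  m <- aln_chars(aln)
  if (nrow(m) == 0L) stop("input error: empty alignment")
  keep <- retained_columns(m, site_policy)
  if (length(keep) == 0L) {
    stop("degenerate-input error: no columns retained under complete-deletion")
  }
  key <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  first <- !duplicated(key)
  classes <- match(key, key[first])
  labels <- sprintf("H%02d", classes)
  names(labels) <- rownames(m)
  counts <- as.integer(table(factor(classes, levels = seq_len(sum(first)))))
  names(counts) <- sprintf("H%02d", seq_len(sum(first)))
  reps <- apply(m[first, , drop = FALSE], 1L, paste, collapse = "")
  names(reps) <- names(counts)
  list(labels = labels, counts = counts, representatives = reps,
       n_retained_sites = length(keep))
}

# ---- population map --------------------------------------------------------

#' Read a population map
#'
#' Two- or three-column tab-separated file with a header: sequence id,
#' locality code and (optionally) haplogroup label. When the haplogroup
#' column is absent each locality is its own haplogroup.
#'
#' Haplogroup membership is taken per individual from this file; the clade
#' assignment itself (e.g. from a phylogenetic tree) is upstream of this
#' package and consumed, not inferred.
#'
#' @param path Path to a TSV file with columns \code{id}, \code{locality}
#'   and optionally \code{haplogroup}.
#' @return A data.frame with columns \code{id}, \code{locality},
#'   \code{haplogroup}.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("input error: population map needs >= 2 columns")
  names(df)[1:2] <- c("id", "locality")
  if (ncol(df) >= 3L) names(df)[3] <- "haplogroup"
  else df$haplogroup <- df$locality
  validate_population_map(df)
  df[, c("id", "locality", "haplogroup")]
}

validate_population_map <- function(df) {
  if (anyDuplicated(df$id)) stop("input error: duplicated ids in map")
  loc2grp <- tapply(df$haplogroup, df$locality,
                    function(g) length(unique(g)))
  bad <- names(loc2grp)[loc2grp > 1L]
  if (length(bad)) {
    stop("input error: locality in more than one haplogroup: ",
         paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Write a population map
#' @param map Data frame with \code{id}, \code{locality}, \code{haplogroup}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_population_map <- function(map, path) {
  utils::write.table(map[, c("id", "locality", "haplogroup")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- haplotype-frequency tables -------------------------------------------

#' Parse a haplotype-frequency table
#'
#' Reads a tab-separated table with one row per collecting locality and
#' columns \code{locality}, \code{haplogroup}, an optional declared sample
#' size \code{n}, and a \code{haplotypes} column of comma-separated tokens
#' \code{"H07(3)"} (count 3) or bare \code{"H07"} (count 1).
#'
#' @param path Path to the TSV file. An \code{abbr} column, if present, is
#'   used as the locality code.
#' @param on_mismatch What to do when a declared \code{n} differs from the
#'   sum of the row's haplotype counts: \code{"error"} (default) stops and
#'   names the locality; \code{"declared"} keeps the declared n as the
#'   locality total and flags the row; \code{"tokens"} uses the token sum.
#' @return An object of class \code{haplotype_table}: a list with
#'   \code{rows} (per-locality data.frame), \code{counts} (list of named
#'   integer vectors), and derived totals.
#' @export
parse_haplotype_table <- function(path,
                                  on_mismatch = c("error", "declared",
                                                  "tokens")) {
  on_mismatch <- match.arg(on_mismatch)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locality", "haplogroup", "haplotypes")
  if (!all(need %in% names(df))) {
    stop("input error: haplotype table needs columns ",
         paste(need, collapse = ", "))
  }
  code <- if ("abbr" %in% names(df)) df$abbr else df$locality
  counts <- lapply(df$haplotypes, parse_hap_tokens)
  token_n <- vapply(counts, sum, integer(1L))
  declared <- if ("n" %in% names(df)) as.integer(df$n) else token_n
  mismatch <- declared != token_n
  if (any(mismatch) && on_mismatch == "error") {
    stop("consistency error: declared n differs from haplotype counts at ",
         paste(code[mismatch], collapse = ", "))
  }
  n_used <- if (on_mismatch == "tokens") token_n else declared
  rows <- data.frame(locality = code, haplogroup = df$haplogroup,
                     n = n_used, n_tokens = token_n,
                     flagged = mismatch, stringsAsFactors = FALSE)
  build_haplotype_table(rows, counts)
}

parse_hap_tokens <- function(s) {
  toks <- trimws(strsplit(s, ",")[[1L]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("input error: empty haplotype list")
  m <- regmatches(toks, regexec("^(H[0-9]+)\\s*(?:\\(\\s*([0-9]+)\\s*\\))?$",
                                toks))
  bad <- vapply(m, length, integer(1L)) == 0L
  if (any(bad)) stop("input error: malformed haplotype token: ",
                     paste(toks[bad], collapse = ", "))
  labs <- vapply(m, `[`, character(1L), 2L)
  cnt <- vapply(m, `[`, character(1L), 3L)
  cnt <- ifelse(cnt == "", "1", cnt)
  cnt <- as.integer(cnt)
  if (any(cnt < 1L)) stop("input error: haplotype counts must be positive")
  if (anyDuplicated(labs)) stop("input error: repeated haplotype in a row")
  stats::setNames(cnt, labs)
}

build_haplotype_table <- function(rows, counts) {
  stopifnot(nrow(rows) == length(counts))
  labels <- sort(unique(unlist(lapply(counts, names))))
  group_n <- tapply(rows$n, rows$haplogroup, sum)
  obj <- list(rows = rows, counts = counts, haplotype_labels = labels,
              locality_totals = stats::setNames(rows$n, rows$locality),
              group_totals = group_n[order(names(group_n))],
              grand_total = sum(rows$n))
  class(obj) <- "haplotype_table"
  obj
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype-frequency table:", nrow(x$rows), "localities,",
      x$grand_total, "individuals,",
      length(x$haplotype_labels), "haplotypes\n")
  gt <- x$group_totals
  cat("Haplogroups:",
      paste(sprintf("%s (n=%d)", names(gt), gt), collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype counts pooled over a set of rows
#'
#' @param ht A \code{haplotype_table}.
#' @param group Optional haplogroup label; default pools all rows.
#' @return Named integer vector of counts per haplotype label.
#' @export
haplotype_counts <- function(ht, group = NULL) {
  stopifnot(inherits(ht, "haplotype_table"))
  idx <- if (is.null(group)) seq_len(nrow(ht$rows))
         else which(ht$rows$haplogroup == group)
  if (is.null(group) || length(idx)) {
    pooled <- unlist(ht$counts[idx])
    if (is.null(pooled)) return(integer(0))
    tab <- tapply(pooled, names(pooled), sum)
    return(stats::setNames(as.integer(tab), names(tab)))
  }
  stop("lookup error: unknown haplogroup: ", group)
}

#' Serialize a haplotype table back to TSV
#' @param ht A \code{haplotype_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  stopifnot(inherits(ht, "haplotype_table"))
  toks <- vapply(ht$counts, function(cn) {
    paste(ifelse(cn == 1L, names(cn), sprintf("%s(%d)", names(cn), cn)),
          collapse = ", ")
  }, character(1L))
  df <- data.frame(locality = ht$rows$locality,
                   haplogroup = ht$rows$haplogroup,
                   n = ht$rows$n, haplotypes = toks,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- haplogroup restriction ------------------------------------------------

#' Restrict data to one haplogroup
#'
#' @param x A \code{DNAbin} alignment (with \code{map} supplied) or a
#'   \code{haplotype_table}.
#' @param group Haplogroup label to keep.
#' @param map Population map data.frame (needed for alignments).
#' @return Object of the same type restricted to members of \code{group}.
#' @export
subset_by_group <- function(x, group, map = NULL) {
  UseMethod("subset_by_group")
}

#' @export
subset_by_group.haplotype_table <- function(x, group, map = NULL) {
  keep <- x$rows$haplogroup == group
  if (!any(keep)) stop("lookup error: unknown haplogroup: ", group)
  build_haplotype_table(x$rows[keep, , drop = FALSE], x$counts[keep])
}

#' @export
subset_by_group.DNAbin <- function(x, group, map = NULL) {
  if (is.null(map)) stop("input error: population map required")
  x <- as.matrix(x)
  unmapped <- setdiff(rownames(x), map$id)
  if (length(unmapped)) {
    stop("input error: ids missing from population map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  if (!group %in% map$haplogroup) {
    stop("lookup error: unknown haplogroup: ", group)
  }
  ids <- map$id[map$haplogroup == group]
  x[rownames(x) %in% ids, , drop = FALSE]
}
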