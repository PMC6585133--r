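## Alignment input/output and site-pattern compression.

#' Construct a DNA alignment object
#'
#' An alignment is an m x n character matrix over \{A, C, G, T\} with unique
#' taxon names as row names.  Columns containing any other symbol (gaps,
#' ambiguity codes) are removed; lower case is folded to upper case and U is
#' mapped to T.
#'
#' @param chars Character matrix (taxa x sites) of single letters.
#' @param taxa Taxon names; defaults to the row names of `chars`.
#' @return An object of class `"dna_alignment"`: the cleaned character
#'   matrix with attributes `n_removed` (number of columns dropped).
#' @export
dna_alignment <- function(chars, taxa = rownames(chars)) {
  if (is.null(taxa)) stop("taxon names required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  chars <- toupper(as.matrix(chars))
  chars[chars == "U"] <- "T"
  ok <- colSums(!matrix(chars %in% .NUC_ABC, nrow(chars))) == 0
  removed <- sum(!ok)
  chars <- chars[, ok, drop = FALSE]
  rownames(chars) <- taxa
  structure(chars, n_removed = removed, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "taxa,", ncol(x), "sites\n")
  if (attr(x, "n_removed") > 0)
    cat("  (", attr(x, "n_removed"),
        "columns with non-ACGT symbols removed )\n")
  invisible(x)
}

#' Read a DNA alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP (whitespace-delimited names of
#' any length; sequences may wrap over lines).  Columns containing symbols
#' outside \{A, C, G, T\} are removed, with a message reporting the count.
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"`; `"auto"` (default) sniffs the
#'   first non-blank character (`>` means FASTA).
#' @return A [dna_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file: ", path)
  if (format == "auto")
    format <- if (startsWith(trimws(lines[1]), ">")) "fasta" else "phylip"
  if (format == "fasta") {
    hdr <- grep("^>", trimws(lines))
    if (length(hdr) == 0) stop("not a FASTA file: ", path)
    taxa <- sub("^>\\s*", "", trimws(lines[hdr]))
    taxa <- sub("\\s.*$", "", taxa)
    ends <- c(hdr[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      if (hdr[i] + 1 > ends[i]) return("")
      paste(gsub("\\s", "", lines[(hdr[i] + 1):ends[i]]), collapse = "")
    }, "")
  } else {
    head_nums <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    if (length(head_nums) < 2 || any(is.na(head_nums)))
      stop("malformed PHYLIP header: ", lines[1])
    m <- head_nums[1]; nsite <- head_nums[2]
    ## relaxed sequential dialect: a token stream of name then sequence
    ## chunks until the declared length is reached, per taxon
    toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
    taxa <- character(m); seqs <- character(m)
    j <- 1
    for (i in seq_len(m)) {
      if (j > length(toks)) stop("PHYLIP file truncated")
      taxa[i] <- toks[j]; j <- j + 1
      acc <- ""
      while (nchar(acc) < nsite) {
        if (j > length(toks))
          stop("PHYLIP sequences do not match declared length ", nsite)
        acc <- paste0(acc, toks[j]); j <- j + 1
      }
      if (nchar(acc) != nsite)
        stop("PHYLIP sequences do not match declared length ", nsite)
      seqs[i] <- acc
    }
  }
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences have unequal lengths")
  chars <- do.call(rbind, strsplit(seqs, ""))
  aln <- dna_alignment(chars, taxa)
  if (attr(aln, "n_removed") > 0)
    message("read_alignment: removed ", attr(aln, "n_removed"),
            " column(s) containing non-ACGT symbols")
  aln
}

#' Write a DNA alignment
#'
#' @param aln A [dna_alignment()].
#' @param path Output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", rownames(aln)), seqs))
  } else {
    out <- c(paste(nrow(aln), ncol(aln)),
             paste(rownames(aln), seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Compress an alignment to its site-pattern table
#'
#' @param aln A [dna_alignment()].
#' @return A list of class `"site_patterns"` with `patterns` (m x p
#'   character matrix of distinct columns), `counts` (multiplicities,
#'   summing to n), `taxa`, `n`, `m`.
#' @export
compress_patterns <- function(aln) {
  chars <- unclass(aln)
  keys <- apply(chars, 2, paste, collapse = "")
  tab <- table(keys)
  pat <- do.call(cbind, strsplit(names(tab), ""))
  rownames(pat) <- rownames(chars)
  structure(list(patterns = pat, counts = as.integer(tab),
                 taxa = rownames(chars), n = ncol(chars), m = nrow(chars)),
            class = "site_patterns")
}

#' @export
print.site_patterns <- function(x, ...) {
  cat("Site-pattern table:", x$m, "taxa,", x$n, "sites,",
      length(x$counts), "distinct patterns\n")
  invisible(x)
}

## expand a pattern table back to an alignment (testing / bootstrap use)
.expand_patterns <- function(sp) {
  idx <- rep(seq_along(sp$counts), sp$counts)
  dna_alignment(sp$patterns[, idx, drop = FALSE], sp$taxa)
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()].  Trees
#' are stored unrooted (a degree-2 root is suppressed), branch lengths in
#' expected substitutions per site.
#'
#' @param text Newick string (or `file` to read from a file).
#' @param file Optional file path.
#' @return For `read_newick`, an [ape::phylo] object (unrooted); for
#'   `write_newick`, a Newick string.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file = file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  if (ape::is.rooted(tr) && ape::Ntip(tr) > 2) tr <- ape::unroot(tr)
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}
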