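## Reading and writing structures and class-labelled benchmark datasets.
## Formats: dot-bracket strings, Zuker-dialect CT connect files, and
## FASTA-with-structure records (header / sequence / dot-bracket) with an
## optional tab-separated record_id <TAB> class_label manifest.

#' Parse a dot-bracket string
#'
#' Only the round-bracket alphabet `.`, `(`, `)` is accepted. Pseudoknot
#' bracket alphabets (`[`, `{`, letters) are rejected with an error unless
#' `dropPseudoknots = TRUE`, in which case non-round-bracket pairs are removed
#' on input (the analysis scope is pseudoknot-free prediction).
#'
#' @param text Dot-bracket string.
#' @param dropPseudoknots Drop `[]`, `{}`, `<>` and `Aa`-style pairs instead of
#'   erroring.
#' @return A validated [SecondaryStructure-class].
#' @examples
#' basePairs(parseDotBracket("((...))"))
#' @export
parseDotBracket <- function(text, dropPseudoknots = FALSE) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (dropPseudoknots) {
    drop <- !(chars %in% c(".", "(", ")"))
    chars[drop] <- "."
  }
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad))
    stop("unsupported characters in dot-bracket string: ",
         paste(sQuote(bad), collapse = ", "),
         " (pseudoknot alphabets are not supported; see dropPseudoknots)")
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced brackets: unmatched ')' at position ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pi <- c(pi, i); pj <- c(pj, k)
    }
  }
  if (length(stack))
    stop("unbalanced brackets: unmatched '(' at position ", stack[1L])
  SecondaryStructure(length(chars), cbind(pi, pj))
}

#' Write a structure as a dot-bracket string
#'
#' Inverse of [parseDotBracket()]; `writeDotBracket(parseDotBracket(x))`
#' reproduces `x`.
#' @param structure A [SecondaryStructure-class].
#' @export
writeDotBracket <- function(structure) dotBracket(structure)

#' Parse a CT (connect format) record
#'
#' Zuker dialect: a header line `<n> <title>`, then n body lines with six
#' columns: index, base, previous, next, pairing partner (0 when unpaired),
#' historical index. Indices are 1-based. The pairing column must be
#' symmetric; asymmetry, out-of-range indices and crossing pairs are errors
#' that name the offending line.
#'
#' @param text A character scalar (whole record) or character vector of lines.
#' @return A list with elements `sequence` ([RnaSequence-class]) and
#'   `structure` ([SecondaryStructure-class]).
#' @export
parseCT <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT record")
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(n) || n < 1L) stop("CT header must start with the sequence length")
  title <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "ct_record"
  body <- lines[-1L]
  if (length(body) != n)
    stop(sprintf("CT body has %d lines, header declares %d", length(body), n))
  bases <- character(n)
  partner <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1L]]
    if (length(f) < 6L) stop("CT line ", k + 1L, ": expected 6 columns")
    idx <- suppressWarnings(as.integer(f[1L]))
    if (is.na(idx) || idx != k) stop("CT line ", k + 1L, ": index column must be ", k)
    bases[k] <- f[2L]
    pk <- suppressWarnings(as.integer(f[5L]))
    if (is.na(pk) || pk < 0L || pk > n)
      stop("CT line ", k + 1L, ": pairing index out of range")
    partner[k] <- pk
  }
  for (k in seq_len(n)) {
    if (partner[k] > 0L && partner[partner[k]] != k)
      stop("CT line ", k + 1L, ": asymmetric pairing (", k, " -> ", partner[k],
           " but ", partner[k], " -> ", partner[partner[k]], ")")
  }
  sel <- which(partner > seq_len(n))
  structure <- tryCatch(
    SecondaryStructure(n, cbind(sel, partner[sel])),
    error = function(e) stop("invalid CT structure: ", conditionMessage(e), call. = FALSE))
  list(sequence = RnaSequence(paste(bases, collapse = ""), id = title),
       structure = structure)
}

#' Write a sequence/structure pair as a CT record
#'
#' @param sequence An [RnaSequence-class] (or character string).
#' @param structure A [SecondaryStructure-class].
#' @param title Header title; defaults to the sequence id.
#' @return Character vector of CT lines.
#' @export
writeCT <- function(sequence, structure, title = NULL) {
  if (is.character(sequence)) sequence <- RnaSequence(sequence)
  n <- nchar(sequence@residues)
  if (n != structure@n) stop("sequence and structure lengths differ")
  if (is.null(title)) title <- sequence@id
  partner <- integer(n)
  if (nrow(structure@pairs)) {
    partner[structure@pairs[, 1L]] <- structure@pairs[, 2L]
    partner[structure@pairs[, 2L]] <- structure@pairs[, 1L]
  }
  bases <- strsplit(sequence@residues, "")[[1L]]
  c(paste(n, title),
    sprintf("%d %s %d %d %d %d", seq_len(n), bases,
            seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L)[seq_len(n)],
            partner, seq_len(n)))
}

#' Read a class-labelled benchmark dataset
#'
#' The file holds FASTA-with-structure records: a `>` header (with an optional
#' `class=<label>` token), the sequence line, and the dot-bracket line. Class
#' labels may instead (or additionally) come from a tab-separated manifest
#' `record_id<TAB>class_label`; manifest labels take precedence.
#'
#' @param path Path to the FASTA-with-structure file.
#' @param manifest Optional path to the manifest TSV.
#' @param name Dataset name; defaults to the file name.
#' @param dropPseudoknots Passed to [parseDotBracket()].
#' @return A [BenchmarkDataset-class]; record order follows the file.
#' @export
readBenchmarkDataset <- function(path, manifest = NULL, name = NULL,
                                 dropPseudoknots = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at)) stop("no FASTA headers found in ", path)
  if (any(diff(hdr_at) != 3L) || hdr_at[1L] != 1L ||
      length(lines) != hdr_at[length(hdr_at)] + 2L)
    stop("each record must be exactly: header, sequence line, structure line")
  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.table(manifest, sep = "\t", header = FALSE,
                             col.names = c("record_id", "class_label"),
                             colClasses = "character", quote = "")
  }
  records <- vector("list", length(hdr_at))
  for (k in seq_along(hdr_at)) {
    hdr <- sub("^>\\s*", "", lines[hdr_at[k]])
    toks <- strsplit(hdr, "\\s+")[[1L]]
    id <- toks[1L]
    lab <- NA_character_
    cl <- grep("^class=", toks, value = TRUE)
    if (length(cl)) lab <- sub("^class=", "", cl[1L])
    if (!is.null(man)) {
      hit <- match(id, man$record_id)
      if (!is.na(hit)) lab <- man$class_label[hit]
    }
    seq <- RnaSequence(lines[hdr_at[k] + 1L], id = id, classLabel = lab)
    db <- lines[hdr_at[k] + 2L]
    if (nchar(db) != nchar(seq@residues))
      stop(sprintf("record '%s': structure length %d differs from sequence length %d",
                   id, nchar(db), nchar(seq@residues)))
    st <- parseDotBracket(db, dropPseudoknots = dropPseudoknots)
    records[[k]] <- ReferenceRecord(seq, st)
  }
  if (!is.null(man)) {
    ids <- vapply(records, function(r) r@sequence@id, character(1))
    unknown <- setdiff(man$record_id, ids)
    if (length(unknown))
      stop("manifest names unknown record(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(name)) name <- basename(path)
  BenchmarkDataset(records, name = name)
}

#' Write a benchmark dataset as FASTA-with-structure (+ optional manifest)
#'
#' @param dataset A [BenchmarkDataset-class].
#' @param path Output file.
#' @param manifest Optional path for the record/class manifest TSV.
#' @param predictions Optional algorithm name: write that prediction instead
#'   of the reference structure (for `evaluate`-style round trips).
#' @export
writeBenchmarkDataset <- function(dataset, path, manifest = NULL,
                                  predictions = NULL) {
  out <- character(0)
  for (r in dataset@records) {
    lab <- r@sequence@classLabel
    hdr <- paste0(">", r@sequence@id,
                  if (!is.na(lab)) paste0(" class=", lab) else "")
    st <- if (is.null(predictions)) r@reference else {
      if (is.null(r@predictions[[predictions]]))
        stop("record '", r@sequence@id, "' has no prediction '", predictions, "'")
      r@predictions[[predictions]]
    }
    out <- c(out, hdr, r@sequence@residues, dotBracket(st))
  }
  writeLines(out, path)
  if (!is.null(manifest)) {
    ids <- vapply(dataset@records, function(r) r@sequence@id, character(1))
    labs <- vapply(dataset@records, function(r) r@sequence@classLabel, character(1))
    writeLines(paste(ids, labs, sep = "\t"), manifest)
  }
  invisible(path)
}
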