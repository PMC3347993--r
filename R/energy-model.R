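## The reduced additive nearest-neighbor model: parameter file I/O, loop
## decomposition, and structure free energy as the sum of per-loop energies.
## Two illustrative parameter sets ship with the package: "toy37" and
## "toy37_alt" (a perturbed variant so parameter-set comparisons can be
## exercised). Neither claims Turner values.

.ALLOWED_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

.base_code <- function(chars) {
  code <- match(chars, c("A", "C", "G", "U")) - 1L
  code[is.na(code)] <- 4L  # N
  code
}

.pair_name <- function(a, b) {
  nm <- paste0(a, b)
  ifelse(nm %in% .ALLOWED_PAIRS, nm, NA_character_)
}

.encode_sequence <- function(sequence) {
  if (is(sequence, "RnaSequence")) sequence <- sequence@residues
  .base_code(strsplit(sequence, "", fixed = TRUE)[[1L]])
}

## list form consumed by the C++ DP
.model_list <- function(params, maxLoop = 30L) {
  list(RT = params@RT, stack = unname(params@stack),
       hairpin = params@hairpin, bulge = params@bulge,
       internal = params@internal,
       ml_a = unname(params@multiloop["a"]),
       ml_b = unname(params@multiloop["b"]),
       ml_c = unname(params@multiloop["c"]),
       terminal_au = params@terminalAU, ln_coeff = params@lnCoeff,
       max_loop = as.integer(maxLoop))
}

#' Load a nearest-neighbor parameter set from a JSON file
#'
#' The schema has sections `meta{name,RT}`, `stack` (map from
#' `"<outer>/<inner>"` pair names, e.g. `"GC/GC"`, to kcal/mol), `hairpin_len`,
#' `bulge_len`, `internal_len` (length-31 arrays for loop sizes 0..30),
#' `multiloop{a,b,c}`, `terminal_au` and `ln_coeff` (the coefficient of the
#' `ln(len/30)` long-loop extrapolation). Missing sections, non-numeric
#' entries and unknown pair keys are errors naming the offender.
#'
#' @param path File path, or one of the packaged set names `"toy37"`,
#'   `"toy37_alt"`.
#' @return An [NNParameterSet-class].
#' @examples
#' p <- loadParameters("toy37")
#' p@RT
#' @export
loadParameters <- function(path) {
  if (path %in% c("toy37", "toy37_alt"))
    path <- system.file("extdata", paste0(path, ".json"),
                        package = "RNAfoldBench", mustWork = TRUE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("meta", "stack", "hairpin_len", "bulge_len", "internal_len",
            "multiloop", "terminal_au", "ln_coeff")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("parameter file missing section(s): ", paste(miss, collapse = ", "))
  if (is.null(obj$meta$name) || is.null(obj$meta$RT))
    stop("meta section must provide name and RT")
  stack <- matrix(0, 6, 6, dimnames = list(.ALLOWED_PAIRS, .ALLOWED_PAIRS))
  for (key in names(obj$stack)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% .ALLOWED_PAIRS))
      stop("unknown stack key '", key, "' (expected e.g. \"GC/GC\")")
    v <- obj$stack[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("non-numeric stack entry for '", key, "'")
    stack[parts[1L], parts[2L]] <- v
  }
  arr <- function(nm) {
    v <- obj[[nm]]
    if (!is.numeric(v) || length(v) != 31L || any(is.na(v)))
      stop(nm, " must be a numeric array of 31 entries (loop sizes 0..30)")
    as.numeric(v)
  }
  ml <- obj$multiloop
  if (!all(c("a", "b", "c") %in% names(ml)))
    stop("multiloop section must provide a, b and c")
  NNParameterSet(name = obj$meta$name, RT = as.numeric(obj$meta$RT),
                 stack = stack, hairpin = arr("hairpin_len"),
                 bulge = arr("bulge_len"), internal = arr("internal_len"),
                 multiloop = c(a = as.numeric(ml$a), b = as.numeric(ml$b),
                               c = as.numeric(ml$c)),
                 terminalAU = as.numeric(obj$terminal_au),
                 lnCoeff = as.numeric(obj$ln_coeff))
}

#' Write a parameter set to the JSON schema read by [loadParameters()]
#'
#' `loadParameters(writeParameters(p, f))` reproduces `p`.
#' @param params An [NNParameterSet-class].
#' @param path Output file.
#' @export
writeParameters <- function(params, path) {
  stack <- list()
  for (a in .ALLOWED_PAIRS) for (b in .ALLOWED_PAIRS)
    if (params@stack[a, b] != 0) stack[[paste0(a, "/", b)]] <- params@stack[a, b]
  if (!length(stack)) stack[["GC/GC"]] <- 0
  obj <- list(meta = list(name = params@name, RT = params@RT),
              stack = stack,
              hairpin_len = params@hairpin, bulge_len = params@bulge,
              internal_len = params@internal,
              multiloop = list(a = unname(params@multiloop["a"]),
                               b = unname(params@multiloop["b"]),
                               c = unname(params@multiloop["c"])),
              terminal_au = params@terminalAU, ln_coeff = params@lnCoeff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.loop_pen <- function(tab, len, lnCoeff) {
  if (len <= 30L) tab[len + 1L] else tab[31L] + lnCoeff * log(len / 30)
}

.is_au_like <- function(pairName) pairName %in% c("AU", "UA", "GU", "UG")

#' Nearest-neighbor loop decomposition of a structure
#'
#' Partitions a structure into its loops: every base pair closes exactly one
#' loop (hairpin, stack, bulge, internal or multiloop) and the external bases
#' and top-level helices form the exterior loop. The number of hairpin loops
#' equals the number of pairs containing no nested pair; the empty structure
#' decomposes into a single exterior loop.
#'
#' @param structure A [SecondaryStructure-class].
#' @return A list of loops; each loop is a list with `type`, `closing` (the
#'   closing pair, or `NULL` for the exterior loop), `branches` (matrix of
#'   directly nested pairs) and `unpaired` (count of unpaired bases in the
#'   loop).
#' @export
loopDecomposition <- function(structure) {
  n <- structure@n
  p <- structure@pairs
  loops <- list()
  ## children of the interval (i, j) = maximal pairs strictly inside
  children <- function(i, j) {
    if (!nrow(p)) return(matrix(integer(), ncol = 2L))
    inside <- p[p[, 1L] > i & p[, 2L] < j, , drop = FALSE]
    if (!nrow(inside)) return(inside)
    keep <- rep(TRUE, nrow(inside))
    for (k in seq_len(nrow(inside))) {
      enclosed <- inside[, 1L] < inside[k, 1L] & inside[, 2L] > inside[k, 2L]
      if (any(enclosed)) keep[k] <- FALSE
    }
    inside[keep, , drop = FALSE]
  }
  walk <- function(i, j) {
    i <- unname(i); j <- unname(j)
    ch <- children(i, j)
    m <- nrow(ch)
    unpaired <- (j - i - 1L) - if (m) sum(ch[, 2L] - ch[, 1L] + 1L) else 0L
    type <- if (m == 0L) "hairpin"
    else if (m == 1L && ch[1L, 1L] == i + 1L && ch[1L, 2L] == j - 1L) "stack"
    else if (m == 1L) {
      b1 <- ch[1L, 1L] - i - 1L
      b2 <- j - ch[1L, 2L] - 1L
      if (b1 == 0L || b2 == 0L) "bulge" else "internal"
    } else "multiloop"
    loops[[length(loops) + 1L]] <<- list(type = type, closing = c(i, j),
                                         branches = ch,
                                         unpaired = as.integer(unpaired))
    for (k in seq_len(m)) walk(ch[k, 1L], ch[k, 2L])
  }
  top <- children(0L, n + 1L)
  unpaired_ext <- n - if (nrow(top)) sum(top[, 2L] - top[, 1L] + 1L) else 0L
  loops[[1L]] <- list(type = "exterior", closing = NULL, branches = top,
                      unpaired = as.integer(unpaired_ext))
  for (k in seq_len(nrow(top))) walk(top[k, 1L], top[k, 2L])
  loops
}

.pair_names_of <- function(sequence, pairs) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!nrow(pairs)) return(character(0))
  .pair_name(chars[pairs[, 1L]], chars[pairs[, 2L]])
}

#' Per-loop free energy
#'
#' Energy of one loop from [loopDecomposition()] under the model conventions:
#' stacks use the stacking table; hairpin/bulge/internal loops use the
#' length-penalty arrays with log extrapolation beyond size 30; multiloops are
#' affine (`a + b` per branch including the closing pair `+ c` per unpaired
#' base); the terminal AU/GU penalty is charged for every AU/UA/GU/UG pair
#' bordering a non-stack loop (closing pairs and branch pairs alike; the
#' exterior loop charges its branches).
#'
#' @param loop One element of a [loopDecomposition()] result.
#' @param sequence Character residues (or [RnaSequence-class]).
#' @param params An [NNParameterSet-class].
#' @return Energy in kcal/mol.
#' @export
loopEnergy <- function(loop, sequence, params) {
  if (is(sequence, "RnaSequence")) sequence <- sequence@residues
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pname <- function(ij) {
    nm <- .pair_name(chars[ij[1L]], chars[ij[2L]])
    if (is.na(nm))
      stop(sprintf("disallowed base pair %s%s at (%d, %d)",
                   chars[ij[1L]], chars[ij[2L]], ij[1L], ij[2L]))
    nm
  }
  au <- function(nm) if (.is_au_like(nm)) params@terminalAU else 0
  br_names <- if (nrow(loop$branches))
    apply(loop$branches, 1L, pname) else character(0)
  switch(loop$type,
    exterior = sum(vapply(br_names, au, numeric(1))),
    hairpin = .loop_pen(params@hairpin, loop$unpaired, params@lnCoeff) +
      au(pname(loop$closing)),
    stack = params@stack[pname(loop$closing), br_names[1L]],
    bulge = .loop_pen(params@bulge, loop$unpaired, params@lnCoeff) +
      au(pname(loop$closing)) + au(br_names[1L]),
    internal = .loop_pen(params@internal, loop$unpaired, params@lnCoeff) +
      au(pname(loop$closing)) + au(br_names[1L]),
    multiloop = params@multiloop["a"] + params@multiloop["b"] +
      loop$unpaired * params@multiloop["c"] + au(pname(loop$closing)) +
      sum(params@multiloop["b"] + vapply(br_names, au, numeric(1))),
    stop("unknown loop type ", loop$type)) |> unname()
}

#' @rdname freeEnergy
#' @examples
#' p <- loadParameters("toy37")
#' freeEnergy("GGAAACC", parseDotBracket("((...))"), p)
#' @export
setMethod("freeEnergy", signature(sequence = "RnaSequence"),
          function(sequence, structure, params)
            freeEnergy(sequence@residues, structure, params))

#' @rdname freeEnergy
#' @export
setMethod("freeEnergy", signature(sequence = "character"),
          function(sequence, structure, params) {
  if (nchar(sequence) != structure@n)
    stop("sequence and structure lengths differ")
  nm <- .pair_names_of(toupper(chartr("tT", "uU", sequence)), structure@pairs)
  if (any(is.na(nm))) {
    bad <- which(is.na(nm))[1L]
    stop(sprintf("structure incompatible with sequence: disallowed pair at (%d, %d)",
                 structure@pairs[bad, 1L], structure@pairs[bad, 2L]))
  }
  if (!nrow(structure@pairs)) return(0)
  loops <- loopDecomposition(structure)
  sum(vapply(loops, loopEnergy, numeric(1),
             sequence = toupper(chartr("tT", "uU", sequence)), params = params))
})
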