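# Short-linear-motif (SLiM) scanning: the PPXXF Homer-binding motif screen.

#' Define a short linear motif pattern
#'
#' A pattern is an ordered list of per-position residue constraints: an
#' uppercase letter fixes that position to one amino acid; `x`, `X` is not
#' allowed as a fixed residue, and a lowercase `x` or a `.` marks a wildcard
#' that any residue (including the ambiguity code `X`) satisfies.  The
#' default `"PPxxF"` is the five-residue Homer EVH1 ligand motif
#' (Pro-Pro-any-any-Phe).
#'
#' @param pattern character scalar, e.g. `"PPxxF"`.
#' @param name optional display name; defaults to the pattern string.
#' @return An object of class `slim_pattern`: list with `name`, `length`,
#'   and `positions` (character vector, `NA` at wildcard positions).
#' @examples
#' slim_pattern("PPxxF")
#' @export
slim_pattern <- function(pattern = "PPxxF", name = pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  positions <- vapply(chars, function(ch) {
    if (ch %in% c("x", ".")) return(NA_character_)
    up <- toupper(ch)
    if (!up %in% AA_CANONICAL) {
      stop_domain("invalid pattern character '", ch,
                  "': use a canonical amino-acid letter, 'x' or '.'")
    }
    if (ch == toupper(ch)) up else NA_character_
  }, character(1), USE.NAMES = FALSE)
  structure(list(name = name, length = length(positions), positions = positions),
            class = "slim_pattern")
}

#' @export
print.slim_pattern <- function(x, ...) {
  shown <- ifelse(is.na(x$positions), "x", x$positions)
  cat("<slim_pattern> ", x$name, ": ", paste(shown, collapse = ""),
      " (length ", x$length, ")\n", sep = "")
  invisible(x)
}

as_slim_pattern <- function(pattern) {
  if (inherits(pattern, "slim_pattern")) pattern else slim_pattern(pattern)
}

#' Validate a protein sequence
#'
#' Sequences must be non-empty, free of whitespace and contain only the 20
#' canonical amino-acid letters plus the ambiguity code `X`.  The first
#' offending position is named in the error.
#'
#' @param sequence character scalar.
#' @param id identifier used in error messages.
#' @return The validated uppercase sequence, invisibly usable.
#' @export
validate_sequence <- function(sequence, id = "protein") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_domain("sequence of '", id, "' must be a non-empty string")
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars %in% c(AA_CANONICAL, "X")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_domain("invalid residue '", chars[bad], "' at position ", bad,
                " of '", id, "'")
  }
  sequence
}

# Translate a slim_pattern to a PCRE lookahead that reports overlapping
# matches.  Wildcards become "." (input is pre-validated to [A-Z]);
# fixed positions are literal letters, so an "X" in the sequence can never
# satisfy them.
pattern_regex <- function(pattern) {
  body <- paste(ifelse(is.na(pattern$positions), ".", pattern$positions),
                collapse = "")
  paste0("(?=", body, ")")
}

#' Scan one protein sequence for a motif
#'
#' Reports every occurrence, including overlapping ones, with 1-based
#' inclusive coordinates (the convention in which the ankyrin-G 190 motif
#' sits at residues 1605-1609).  A pattern longer than the sequence yields
#' an empty table, not an error.
#'
#' @param sequence amino-acid string (validated; `X` allowed).
#' @param pattern a [slim_pattern()] or pattern string.
#' @param id protein identifier recorded in the hit table.
#' @return data.frame with columns `protein_id`, `start`, `end`, `matched`,
#'   `pattern`, sorted by `start`.
#' @examples
#' scan_sequence("PPPAFF", "PPxxF")   # two overlapping hits
#' @export
scan_sequence <- function(sequence, pattern = slim_pattern(), id = "protein") {
  pattern <- as_slim_pattern(pattern)
  sequence <- validate_sequence(sequence, id)
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      pattern = character(), stringsAsFactors = FALSE)
  if (pattern$length > nchar(sequence)) return(empty)
  m <- gregexpr(pattern_regex(pattern), sequence, perl = TRUE)[[1]]
  starts <- as.integer(m)
  if (length(starts) == 1L && starts[1] == -1L) return(empty)
  ends <- starts + pattern$length - 1L
  data.frame(protein_id = id, start = starts, end = ends,
             matched = substring(sequence, starts, ends),
             pattern = pattern$name, stringsAsFactors = FALSE)
}

#' Scan a whole proteome for a motif
#'
#' @param proteome data.frame with columns `id` and `sequence` (and
#'   optionally `species`), e.g. from [read_proteome_fasta()] or
#'   [gen_motif_proteome()].
#' @param pattern a [slim_pattern()] or pattern string.
#' @return A single hit table (see [scan_sequence()]); zero-row if no
#'   protein carries the motif.
#' @export
scan_proteome <- function(proteome, pattern = slim_pattern()) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  if (anyDuplicated(proteome$id)) {
    stop_domain("protein ids must be unique within a proteome")
  }
  pattern <- as_slim_pattern(pattern)
  hits <- lapply(seq_len(nrow(proteome)), function(i) {
    scan_sequence(proteome$sequence[i], pattern, id = proteome$id[i])
  })
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Re-scan a sequence under a point substitution
#'
#' Models point-mutation controls such as ankyrin-G P1606L and F1609R:
#' substitute exactly one residue and report motif hits before and after.
#'
#' @param sequence amino-acid string.
#' @param position 1-based residue index to substitute.
#' @param new_residue a canonical amino-acid letter.
#' @param pattern a [slim_pattern()] or pattern string.
#' @param id protein identifier.
#' @return list with `before` and `after` hit tables and `mutated_sequence`.
#' @examples
#' rescan_with_substitution("PPAAF", 5, "R")  # F5R destroys the motif
#' @export
rescan_with_substitution <- function(sequence, position, new_residue,
                                     pattern = slim_pattern(), id = "protein") {
  sequence <- validate_sequence(sequence, id)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > nchar(sequence) || position != round(position)) {
    stop_domain("position ", position, " out of range 1..", nchar(sequence))
  }
  new_residue <- toupper(new_residue)
  if (!new_residue %in% AA_CANONICAL) {
    stop_domain("new_residue must be a canonical amino acid, got '",
                new_residue, "'")
  }
  mutated <- sequence
  substr(mutated, position, position) <- new_residue
  list(before = scan_sequence(sequence, pattern, id),
       after = scan_sequence(mutated, pattern, id),
       mutated_sequence = mutated)
}

#' Cross-species conservation filter for motif presence
#'
#' Implements the four-species conservation step of the screen: an ortholog
#' group passes when every required species' ortholog carries the motif.
#' Two criteria are available: `"presence"` (default) requires at least one
#' hit anywhere in each required ortholog; `"positional"` additionally
#' requires that a common motif location exists, i.e. some residue index has
#' a hit start within `window` residues of it in every species, which
#' approximates an alignment-based check without running an aligner.
#'
#' Groups missing a required species are reported as non-conserved with a
#' warning rather than an error.
#'
#' @param groups long-format data.frame with columns `group_id`, `species`,
#'   `sequence` (one row per ortholog), e.g. from [gen_ortholog_groups()].
#' @param pattern a [slim_pattern()] or pattern string.
#' @param required_species species that must all carry the motif; default
#'   the study's human/bovine/mouse/rat panel.
#' @param mode `"presence"` or `"positional"`.
#' @param window half-width (residues) of the positional tolerance.
#' @return Sorted character vector of conserved `group_id`s, with a
#'   `details` attribute (per-group per-species hit counts).
#' @export
conservation_filter <- function(groups, pattern = slim_pattern(),
                                required_species = c("human", "bovine",
                                                     "mouse", "rat"),
                                mode = c("presence", "positional"),
                                window = 30L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(groups),
            all(c("group_id", "species", "sequence") %in% names(groups)))
  pattern <- as_slim_pattern(pattern)
  ids <- sort(unique(groups$group_id))
  details <- list()
  conserved <- logical(length(ids))
  names(conserved) <- ids
  for (g in ids) {
    sub <- groups[groups$group_id == g, , drop = FALSE]
    if (anyDuplicated(sub$species)) {
      stop_domain("group '", g, "' has duplicated species labels")
    }
    missing <- setdiff(required_species, sub$species)
    if (length(missing)) {
      warning("group '", g, "' is missing required species: ",
              paste(missing, collapse = ", "), "; treated as non-conserved",
              call. = FALSE)
      conserved[g] <- FALSE
      next
    }
    starts <- lapply(required_species, function(sp) {
      seq_i <- sub$sequence[sub$species == sp][1]
      scan_sequence(seq_i, pattern, id = paste0(g, ":", sp))$start
    })
    names(starts) <- required_species
    details[[g]] <- vapply(starts, length, integer(1))
    if (any(vapply(starts, length, integer(1)) == 0L)) {
      conserved[g] <- FALSE
    } else if (mode == "presence") {
      conserved[g] <- TRUE
    } else {
      # positional: some candidate anchor has a hit within +/- window in
      # every species; candidates are all observed hit starts.
      anchors <- sort(unique(unlist(starts)))
      conserved[g] <- any(vapply(anchors, function(a) {
        all(vapply(starts, function(s) any(abs(s - a) <= window), logical(1)))
      }, logical(1)))
    }
  }
  out <- names(conserved)[conserved]
  attr(out, "details") <- details
  out
}

# ---- FASTA and table I/O ----------------------------------------------------

#' Read a proteome from FASTA
#'
#' The record description is parsed as `<id> [species=<label>] [free text]`;
#' a missing `species=` token yields `NA`.
#'
#' @param path FASTA file (one record per protein).
#' @return data.frame with columns `id`, `species`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  id <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("species=\\S+", h))
    if (length(m)) sub("^species=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(id = id, species = species,
                    sequence = as.character(aas), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (anyDuplicated(out$id)) stop_domain("duplicate protein ids in ", path)
  for (i in seq_len(nrow(out))) validate_sequence(out$sequence[i], out$id[i])
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome data.frame with `id`, `sequence` and optionally `species`.
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  headers <- proteome$id
  if (!is.null(proteome$species)) {
    has_sp <- !is.na(proteome$species)
    headers[has_sp] <- paste0(headers[has_sp], " species=",
                              proteome$species[has_sp])
  }
  aas <- Biostrings::AAStringSet(proteome$sequence)
  names(aas) <- headers
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Write a motif hit table to TSV
#'
#' @param hits hit table from [scan_sequence()] / [scan_proteome()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
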