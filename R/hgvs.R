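#' Parse an HGVS coding-DNA variant description
#'
#' Parses the coding-DNA (\code{c.}) subset of HGVS nomenclature used to
#' describe germline point mutations and small indels: substitutions
#' (\code{c.535C>T}), deletions (\code{c.67delG},
#' \code{c.5722_5723delCT}), insertions (\code{c.10_11insAT}),
#' deletion-insertions (\code{c.10_12delinsGG}) and duplications
#' (\code{c.10dupA}). Positions with intronic offsets such as
#' \code{c.711+4A>T} are recognized and flagged \code{intronic = TRUE}
#' rather than silently coerced to a coding position.
#'
#' @param text A single HGVS string, optionally prefixed by a transcript
#'   identifier (\code{"NM_000136.2:c.535C>T"}).
#' @return An object of class \code{cdna_variant}: a list with
#'   \code{transcript_id}, \code{kind} (one of \code{"substitution"},
#'   \code{"deletion"}, \code{"insertion"}, \code{"delins"},
#'   \code{"duplication"}), 1-based coding positions \code{start} and
#'   \code{end}, \code{ref_bases}/\code{alt_bases} (\code{NA} when not
#'   stated), and logical \code{intronic}.
#' @examples
#' parse_cdna_hgvs("c.535C>T")
#' parse_cdna_hgvs("NM_000059:c.5722_5723delCT")
#' parse_cdna_hgvs("c.711+4A>T")$intronic
#' @export
parse_cdna_hgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  raw <- trimws(text)
  body <- raw
  transcript_id <- NA_character_
  if (grepl(":", body, fixed = TRUE)) {
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("HGVS parse error in '", raw, "': unexpected token '",
           parts[3], "'", call. = FALSE)
    }
    transcript_id <- parts[1]
    body <- parts[2]
  }
  if (!startsWith(body, "c.")) {
    stop("HGVS parse error in '", raw, "': expected 'c.' prefix, got '",
         substr(body, 1, 2), "'", call. = FALSE)
  }
  body <- substring(body, 3)

  pos_re <- "(\\d+)([+-]\\d+)?"
  span_re <- paste0("^", pos_re, "(?:_", pos_re, ")?")
  m <- regexpr(span_re, body, perl = TRUE)
  if (m == -1L) {
    stop("HGVS parse error in '", raw, "': expected a cDNA position, got '",
         body, "'", call. = FALSE)
  }
  span <- regmatches(body, m)
  rest <- substring(body, attr(m, "match.length") + 1L)
  nums <- regmatches(span, gregexpr(pos_re, span, perl = TRUE))[[1]]
  p1 <- nums[1]
  p2 <- if (length(nums) > 1L) nums[2] else nums[1]
  split_pos <- function(tok) {
    base <- as.integer(sub("([+-].*)$", "", tok))
    off <- if (grepl("[+-]", tok)) as.integer(sub("^\\d+", "", tok)) else 0L
    c(base, off)
  }
  s <- split_pos(p1)
  e <- split_pos(p2)
  intronic <- s[2] != 0L || e[2] != 0L

  kind <- NULL
  ref_bases <- NA_character_
  alt_bases <- NA_character_
  if (grepl("^[ACGT]>[ACGT]$", rest)) {
    kind <- "substitution"
    ref_bases <- substr(rest, 1, 1)
    alt_bases <- substr(rest, 3, 3)
    if (s[1] != e[1] || s[2] != e[2]) {
      stop("HGVS parse error in '", raw,
           "': substitution must have a single position", call. = FALSE)
    }
  } else if (grepl("^del[ACGT]*ins[ACGT]+$", rest)) {
    kind <- "delins"
    ref_bases <- sub("^del([ACGT]*)ins.*$", "\\1", rest)
    if (ref_bases == "") ref_bases <- NA_character_
    alt_bases <- sub("^del[ACGT]*ins", "", rest)
  } else if (grepl("^del[ACGT]*$", rest)) {
    kind <- "deletion"
    ref_bases <- sub("^del", "", rest)
    if (ref_bases == "") ref_bases <- NA_character_
  } else if (grepl("^ins[ACGT]+$", rest)) {
    kind <- "insertion"
    alt_bases <- sub("^ins", "", rest)
  } else if (grepl("^dup[ACGT]*$", rest)) {
    kind <- "duplication"
    ref_bases <- sub("^dup", "", rest)
    if (ref_bases == "") ref_bases <- NA_character_
  } else {
    stop("HGVS parse error in '", raw, "': unrecognized edit '", rest, "'",
         call. = FALSE)
  }
  if (s[1] > e[1]) {
    stop("HGVS parse error in '", raw, "': start position after end",
         call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, kind = kind,
         start = s[1], end = e[1],
         start_offset = s[2], end_offset = e[2],
         ref_bases = ref_bases, alt_bases = alt_bases,
         intronic = intronic, input = raw),
    class = "cdna_variant"
  )
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat("<cdna_variant> ", x$input, "\n", sep = "")
  cat("  kind: ", x$kind, "  c.", x$start,
      if (x$end != x$start) paste0("_", x$end) else "",
      if (x$intronic) "  [intronic offset]" else "", "\n", sep = "")
  invisible(x)
}

#' Codon index of a coding-DNA position
#'
#' Maps a 1-based coding-DNA (CDS) position to the 1-based index of the
#' codon containing it: positions 1-3 fall in codon 1, 4-6 in codon 2,
#' and in general \code{floor((c_pos - 1) / 3) + 1}. This is the residue
#' number paired with a cDNA position in HGVS protein notation (e.g. a
#' substitution at c.553 alters codon 185).
#'
#' @param c_pos Integer vector of coding cDNA positions (>= 1).
#' @return Integer vector of codon indices.
#' @examples
#' codon_of(c(1, 3, 4))   # 1 1 2
#' codon_of(553)          # 185
#' @export
codon_of <- function(c_pos) {
  c_pos <- as.numeric(c_pos)
  if (any(is.na(c_pos)) || any(c_pos < 1) || any(c_pos != floor(c_pos))) {
    stop("coding cDNA positions must be integers >= 1", call. = FALSE)
  }
  as.integer((c_pos - 1) %/% 3 + 1)
}

translate_cds <- function(seq) {
  usable <- 3L * (nchar(seq) %/% 3L)
  if (usable == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, usable)),
    no.init.codon = TRUE
  ))
}

apply_cdna_edit <- function(variant, cds) {
  n <- nchar(cds)
  if (variant$start > n || variant$end > n) {
    stop("variant position ", max(variant$start, variant$end),
         " beyond coding sequence end (", n, " nt)", call. = FALSE)
  }
  before <- function(p) substr(cds, 1L, p - 1L)
  after <- function(p) substring(cds, p + 1L)
  switch(variant$kind,
    substitution = paste0(before(variant$start), variant$alt_bases,
                          after(variant$start)),
    deletion = paste0(before(variant$start), after(variant$end)),
    delins = paste0(before(variant$start), variant$alt_bases,
                    after(variant$end)),
    insertion = paste0(substr(cds, 1L, variant$start), variant$alt_bases,
                       substring(cds, variant$start + 1L)),
    duplication = paste0(substr(cds, 1L, variant$end),
                         substr(cds, variant$start, variant$end),
                         substring(cds, variant$end + 1L)),
    stop("unsupported variant kind: ", variant$kind, call. = FALSE)
  )
}

#' Protein-level consequence of a coding-DNA variant
#'
#' Applies a parsed coding-DNA edit to a complete CDS (ATG ... stop),
#' translates the reference and edited sequences, and classifies the
#' protein change. Frameshifts (length change not divisible by 3) report
#' \code{fs_term_offset}, the distance in residues from the first
#' changed residue to the novel termination codon, counting the stop
#' itself (the \code{"fs*23"} convention). If the shifted frame reaches
#' the end of the transcript without a stop, \code{fs_term_offset} is
#' \code{NA} and \code{status} is \code{"no_stop"}.
#'
#' @param variant A \code{cdna_variant} from [parse_cdna_hgvs()].
#' @param coding_sequence Character scalar: the CDS, length divisible by
#'   3, starting \code{ATG} and ending with a stop codon.
#' @return A list of class \code{protein_change} with \code{change_class}
#'   (one of \code{"nonsense"}, \code{"missense"}, \code{"synonymous"},
#'   \code{"frameshift"}, \code{"inframe_indel"}), \code{codon_index}
#'   (first affected codon), \code{ref_residue}, \code{new_residue}
#'   (\code{"*"} for a gained stop), \code{fs_term_offset} and
#'   \code{status}.
#' @export
protein_consequence <- function(variant, coding_sequence) {
  stopifnot(inherits(variant, "cdna_variant"))
  cds <- toupper(coding_sequence)
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  }
  if (substr(cds, 1, 3) != "ATG") {
    stop("coding sequence must start with ATG", call. = FALSE)
  }
  last <- substring(cds, nchar(cds) - 2L)
  if (!last %in% c("TAA", "TAG", "TGA")) {
    stop("coding sequence must end with a stop codon", call. = FALSE)
  }
  if (variant$intronic) {
    stop("intronic cDNA description '", variant$input,
         "' has no coding consequence on a CDS", call. = FALSE)
  }
  if (variant$start > nchar(cds) || variant$end > nchar(cds)) {
    stop("variant position ", max(variant$start, variant$end),
         " beyond coding sequence end (", nchar(cds), " nt)", call. = FALSE)
  }
  if (!is.na(variant$ref_bases)) {
    stated <- substr(cds, variant$start,
                     variant$start + nchar(variant$ref_bases) - 1L)
    if (stated != variant$ref_bases) {
      stop("reference bases in '", variant$input, "' (", variant$ref_bases,
           ") do not match the coding sequence (", stated, ")",
           call. = FALSE)
    }
  }

  edited <- apply_cdna_edit(variant, cds)
  ref_prot <- translate_cds(cds)
  new_prot <- translate_cds(edited)
  len_change <- nchar(edited) - nchar(cds)

  res <- list(codon_index = NA_integer_, change_class = NA_character_,
              ref_residue = NA_character_, new_residue = NA_character_,
              fs_term_offset = NA_integer_, status = "ok")

  if (variant$kind == "substitution") {
    idx <- codon_of(variant$start)
    res$codon_index <- idx
    res$ref_residue <- substr(ref_prot, idx, idx)
    res$new_residue <- substr(new_prot, idx, idx)
    res$change_class <- if (res$new_residue == res$ref_residue) {
      "synonymous"
    } else if (res$new_residue == "*") {
      "nonsense"
    } else {
      "missense"
    }
  } else if (len_change %% 3L == 0L) {
    res$change_class <- "inframe_indel"
    res$codon_index <- codon_of(variant$start)
  } else {
    res$change_class <- "frameshift"
    # first residue where the translations diverge
    nmin <- min(nchar(ref_prot), nchar(new_prot))
    ref_chars <- strsplit(ref_prot, "")[[1]]
    new_chars <- strsplit(new_prot, "")[[1]]
    diff <- which(ref_chars[seq_len(nmin)] != new_chars[seq_len(nmin)])
    first <- if (length(diff)) diff[1] else nmin + 1L
    res$codon_index <- as.integer(first)
    res$ref_residue <- if (first <= nchar(ref_prot)) ref_chars[first] else NA_character_
    res$new_residue <- if (first <= nchar(new_prot)) new_chars[first] else NA_character_
    stop_at <- which(new_chars == "*" & seq_along(new_chars) >= first)
    if (length(stop_at)) {
      res$fs_term_offset <- as.integer(stop_at[1] - first + 1L)
    } else {
      res$status <- "no_stop"
    }
  }
  class(res) <- "protein_change"
  res
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", x$change_class, " at codon ", x$codon_index, sep = "")
  if (!is.na(x$ref_residue)) cat(" (", x$ref_residue, "->", x$new_residue, ")", sep = "")
  if (!is.na(x$fs_term_offset)) cat(" fs*", x$fs_term_offset, sep = "")
  if (x$status != "ok") cat(" [", x$status, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Classify variants as overtly deleterious
#'
#' A variant is overtly deleterious when its predicted consequence is one
#' of the four truncating/disruptive classes - \code{stop_gained},
#' \code{frameshift_coding}, \code{essential_splice_site},
#' \code{complex_indel} - or when it is a registry-validated pathogenic
#' allele (\code{known_pathogenic} flag), which admits functionally
#' proven missense mutations that screening programmes count alongside
#' truncations.
#'
#' @param variants A data frame of annotated variants with a
#'   \code{consequence} column and (optionally) a logical
#'   \code{known_pathogenic} column.
#' @return Logical vector, one element per row.
#' @export
classify_overtly_deleterious <- function(variants) {
  stopifnot(is.data.frame(variants), "consequence" %in% names(variants))
  trunc_classes <- c("stop_gained", "frameshift_coding",
                     "essential_splice_site", "complex_indel")
  hit <- variants$consequence %in% trunc_classes
  if ("known_pathogenic" %in% names(variants)) {
    hit <- hit | (!is.na(variants$known_pathogenic) & variants$known_pathogenic)
  }
  hit
}
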