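#' Normalize a raw sequence string
#'
#' Cleans pasted sequence text (whitespace, digits, case) and validates it
#' against the requested alphabet. `T`/`U` are coerced to the alphabet, so a
#' DNA template pasted with `U`s or an RNA pasted with `T`s round-trips
#' silently; any other character is an error.
#'
#' @param text Raw sequence text. Whitespace and digits (GenBank-style pasted
#'   blocks) are stripped before validation.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return A `plor_seq` object: a single uppercase string over `{A,C,G,T}`
#'   (DNA) or `{A,C,G,U}` (RNA) with an `alphabet` attribute.
#' @examples
#' normalize_sequence("ggga", "RNA")
#' normalize_sequence("GGGT", "RNA") # T -> U
#' @export
normalize_sequence <- function(text, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (length(text) != 1L || !is.character(text)) {
    abort("`text` must be a single character string.")
  }
  s <- toupper(gsub("[[:space:][:digit:]]", "", text))
  if (!nzchar(s)) abort("sequence is empty after whitespace removal")
  s <- if (alphabet == "DNA") chartr("U", "T", s) else chartr("T", "U", s)
  ok <- if (alphabet == "DNA") "ACGT" else "ACGU"
  bad <- regexpr(sprintf("[^%s]", ok), s)
  if (bad > 0L) {
    abort(sprintf(
      "invalid %s character '%s' at position %d",
      alphabet, substr(s, bad, bad), bad
    ))
  }
  structure(s, alphabet = alphabet, class = "plor_seq")
}

#' @export
as.character.plor_seq <- function(x, ...) {
  attributes(x) <- NULL
  unclass(x)
}

#' @export
print.plor_seq <- function(x, ...) {
  cat(sprintf("<%s sequence, %d nt>\n", attr(x, "alphabet"), nchar(x)))
  cat(strwrap(unclass(x), width = 60), sep = "\n")
  invisible(x)
}

seq_alphabet <- function(x) attr(x, "alphabet") %||% "DNA"

as_dna <- function(x) {
  if (inherits(x, "plor_seq") && seq_alphabet(x) == "DNA") x
  else normalize_sequence(as.character(x), "DNA")
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement (via [Biostrings]); an involution,
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq A DNA sequence (string or [normalize_sequence()] output).
#' @return A `plor_seq` DNA sequence.
#' @examples
#' reverse_complement("CCCTATAGTGAGTCGTATTA") # recovers the T7 promoter + GGG
#' @export
reverse_complement <- function(seq) {
  s <- as_dna(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unclass(s))))
  structure(rc, alphabet = "DNA", class = "plor_seq")
}

#' Read a template sequence from FASTA or plain text
#'
#' Single- and multi-record FASTA are read with [Biostrings::readDNAStringSet()];
#' files without a `>` header are treated as pasted plain text (whitespace and
#' line numbers stripped).
#'
#' @param path Path to a FASTA or plain-text sequence file.
#' @param which For multi-record FASTA, the record index or name to use.
#' @return A `plor_seq` DNA sequence; the FASTA description is kept as the
#'   `description` attribute.
#' @export
read_template <- function(path, which = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(first), ">")) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) abort("FASTA file contains no records")
    s <- normalize_sequence(as.character(set[[which]]), "DNA")
    attr(s, "description") <- names(set)[[if (is.character(which)) match(which, names(set)) else which]]
    s
  } else {
    normalize_sequence(paste(readLines(path, warn = FALSE), collapse = ""), "DNA")
  }
}

#' Write sequences to FASTA
#'
#' @param seqs A character vector (or list of `plor_seq`) of sequences.
#' @param path Output file path.
#' @param names Description lines; defaults to `seq1, seq2, ...`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, names = NULL) {
  seqs <- vapply(seqs, function(s) as.character(unclass(s)), character(1))
  names <- names %||% sprintf("seq%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  names(set) <- names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

T7_PROMOTER <- "TAATACGACTCACTATA"

find_sites <- function(s, motif) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(motif, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0L) break
    out <- c(out, from + i - 1L)
    from <- from + i  # overlapping hits allowed
  }
  out
}

#' Locate the T7 promoter on a double-stranded template
#'
#' Scans the given strand and its reverse complement for the 17-nt class-III
#' T7 promoter consensus `TAATACGACTCACTATA`. Transcription initiates at the
#' base immediately following the consensus (+1).
#'
#' @param template A DNA sequence (string, `plor_seq`, or file read with
#'   [read_template()]).
#' @return A list of class `plor_promoter` with fields `strand` (`"given"` or
#'   `"reverse_complement"`), `promoter_start` (1-based position of the 17-mer
#'   on the reported strand) and `txn_start` (`promoter_start + 17`, the +1
#'   position).
#' @examples
#' find_t7_promoter("TAATACGACTCACTATAGGGAAA")
#' @export
find_t7_promoter <- function(template) {
  s <- as_dna(template)
  if (nchar(s) < nchar(T7_PROMOTER) + 1L) {
    abort("template too short to contain a promoter and a transcribed base")
  }
  rc <- reverse_complement(s)
  hits <- rbind(
    if (length(h <- find_sites(unclass(s), T7_PROMOTER)))
      data.frame(strand = "given", promoter_start = h),
    if (length(h <- find_sites(unclass(rc), T7_PROMOTER)))
      data.frame(strand = "reverse_complement", promoter_start = h)
  )
  if (is.null(hits) || nrow(hits) == 0L) abort("promoter not found")
  if (nrow(hits) > 1L) {
    abort(sprintf(
      "ambiguous promoter: %d sites (%s)",
      nrow(hits),
      paste(sprintf("%s:%d", hits$strand, hits$promoter_start), collapse = ", ")
    ))
  }
  structure(
    list(
      strand = hits$strand[[1]],
      promoter_start = hits$promoter_start[[1]],
      txn_start = hits$promoter_start[[1]] + nchar(T7_PROMOTER)
    ),
    class = "plor_promoter"
  )
}

#' @export
print.plor_promoter <- function(x, ...) {
  cat(sprintf(
    "T7 promoter on %s strand at %d; +1 at %d\n",
    x$strand, x$promoter_start, x$txn_start
  ))
  invisible(x)
}

#' Derive the run-off transcript from a template
#'
#' Locates the T7 promoter on either strand and emits the RNA from the +1
#' position to the end of the coding-sense strand (run-off convention: absent
#' termination, the polymerase transcribes to the template end). A transcript
#' that does not begin with G triggers a warning — T7 RNAP strongly prefers G
#' initiation — but is not an error.
#'
#' @inheritParams find_t7_promoter
#' @return A list of class `plor_transcript` with fields `rna` (a `plor_seq`
#'   RNA), `length`, `source_site` (the [find_t7_promoter()] result) and
#'   `template` (the coding-sense DNA strand).
#' @examples
#' tx <- derive_transcript("TAATACGACTCACTATAGGGAAA")
#' tx$length
#' @export
derive_transcript <- function(template) {
  s <- as_dna(template)
  site <- find_t7_promoter(s)
  coding <- if (site$strand == "given") s else reverse_complement(s)
  if (site$txn_start > nchar(coding)) abort("no transcribed bases downstream of promoter")
  rna <- normalize_sequence(substr(coding, site$txn_start, nchar(coding)), "RNA")
  if (substr(rna, 1L, 1L) != "G") {
    warn(sprintf("transcript starts with %s, not G (T7 initiation preference)",
                 substr(rna, 1L, 1L)))
  }
  structure(
    list(rna = rna, length = nchar(rna), source_site = site, template = coding),
    class = "plor_transcript"
  )
}

#' @export
print.plor_transcript <- function(x, ...) {
  cat(sprintf("<PLOR transcript, %d nt; promoter on %s strand, +1 at %d>\n",
              x$length, x$source_site$strand, x$source_site$txn_start))
  cat(strwrap(unclass(x$rna), width = 60), sep = "\n")
  invisible(x)
}

as_transcript <- function(tx) {
  if (inherits(tx, "plor_transcript")) return(tx)
  rna <- normalize_sequence(as.character(tx), "RNA")
  structure(
    list(rna = rna, length = nchar(rna), source_site = NULL, template = NULL),
    class = "plor_transcript"
  )
}

transcript_bases <- function(tx) strsplit(unclass(tx$rna), "")[[1]]

#' Annotate the intrinsic terminator U-tract
#'
#' Intrinsic terminators release the polymerase at a run of consecutive U
#' residues following a GC-rich hairpin; only the U-run is modeled here. The
#' annotation selects the longest maximal run of consecutive U of length at
#' least `min_run`, breaking length ties in favour of the most 3' (downstream)
#' run, and defines the terminated product as the transcript truncated
#' immediately before the run.
#'
#' @param tx A transcript ([derive_transcript()] output or an RNA string).
#' @param min_run Minimum U-run length to qualify as a terminator (default 6).
#' @return A list of class `plor_terminator` with 1-based inclusive transcript
#'   coordinates `u_start`, `u_end`, plus `run_length` and `terminated_length`
#'   (`u_start - 1`).
#' @examples
#' annotate_terminator("GGGUUUUUU")
#' @export
annotate_terminator <- function(tx, min_run = 6L) {
  tx <- as_transcript(tx)
  if (min_run < 1L) abort("`min_run` must be >= 1")
  m <- gregexpr("U+", unclass(tx$rna))[[1]]
  len <- attr(m, "match.length")
  keep <- m > 0L & len >= min_run
  if (!any(keep)) abort(sprintf("no U-tract found (no run of >= %d U)", min_run))
  starts <- as.integer(m[keep])
  lens <- len[keep]
  # longest run; ties -> most downstream
  best <- which(lens == max(lens))
  best <- best[which.max(starts[best])]
  structure(
    list(
      u_start = starts[best],
      u_end = starts[best] + lens[best] - 1L,
      run_length = lens[best],
      terminated_length = starts[best] - 1L
    ),
    class = "plor_terminator"
  )
}

#' @export
print.plor_terminator <- function(x, ...) {
  cat(sprintf("terminator U-tract at %d-%d (%d U); terminated product %d nt\n",
              x$u_start, x$u_end, x$run_length, x$terminated_length))
  invisible(x)
}

#' Packaged example: the adenine riboswitch PLOR template
#'
#' The 155-nt PCR template for the *Bacillus subtilis* pbuE adenine riboswitch
#' construct, with the T7 promoter on the reverse complement of the printed
#' strand. The run-off transcript is 120 nt; the terminator U-tract spans
#' transcript positions 101-108, so the terminated product is 100 nt.
#'
#' @return Path to the packaged FASTA file.
#' @examples
#' tx <- derive_transcript(read_template(plor_example_template()))
#' tx$length
#' @export
plor_example_template <- function() {
  system.file("extdata", "adenine_riboswitch_template.fa", package = "plor",
              mustWork = TRUE)
}
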