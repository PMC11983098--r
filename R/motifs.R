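#' Motif specification
#'
#' Short promoter elements given as IUPAC strings, matched exactly
#' (degenerate IUPAC codes allowed). The two motifs central to
#' growth-regulated promoters are provided by [pac_motif()] (PAC, GATGAG,
#' bound by Dot6/Tod6) and [rrpe_motif()] (RRPE, TGAAAA, bound by Stb3).
#'
#' @param name motif name.
#' @param sequence IUPAC DNA string.
#' @param both_strands also match the reverse complement (default TRUE).
#' @return A `MotifSpec` object.
#' @export
motif_spec <- function(name, sequence, both_strands = TRUE) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", sequence))
    stop("motif sequence must be a non-empty IUPAC DNA string")
  structure(list(name = name, sequence = sequence,
                 both_strands = both_strands),
            class = "MotifSpec")
}

#' @rdname motif_spec
#' @export
pac_motif <- function(both_strands = TRUE)
  motif_spec("PAC", "GATGAG", both_strands)

#' @rdname motif_spec
#' @export
rrpe_motif <- function(both_strands = TRUE)
  motif_spec("RRPE", "TGAAAA", both_strands)

as_dna_set <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) return(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Count motif occurrences per sequence
#'
#' Exact (IUPAC-aware) occurrence counts of a motif in each sequence,
#' summing both strands when the motif asks for it. Case-insensitive.
#'
#' @param seqs named character vector or `DNAStringSet` of promoter
#'   sequences keyed by gene_id.
#' @param motif `MotifSpec`.
#' @return named integer vector of occurrence counts.
#' @export
motif_occurrences <- function(seqs, motif) {
  dna <- as_dna_set(seqs)
  pat <- Biostrings::DNAString(motif$sequence)
  n <- Biostrings::vcountPattern(pat, dna, fixed = FALSE)
  if (motif$both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    if (as.character(rc) != as.character(pat))
      n <- n + Biostrings::vcountPattern(rc, dna, fixed = FALSE)
  }
  short <- Biostrings::width(dna) < length(pat)
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than motif ", motif$name,
            "; scored 0")
    n[short] <- 0L
  }
  setNames(as.integer(n), names(dna))
}

#' Motif enrichment in a foreground vs background promoter set
#'
#' A promoter "has" a motif when it contains at least one exact occurrence
#' (zero-or-one-occurrence-per-sequence counting; total occurrences
#' available via `counting = "total"`). Enrichment is a Fisher exact test on
#' the 2x2 presence table of foreground vs background promoters. By default
#' the background excludes foreground genes. The odds ratio is the sample
#' cross-product ratio, with a Haldane 0.5 correction applied when any cell
#' is zero.
#'
#' @param seqs named character vector or `DNAStringSet` keyed by gene_id.
#' @param motifs list of `MotifSpec` (a single spec is accepted).
#' @param foreground,background character vectors of gene ids; every id
#'   must have a sequence.
#' @param exclude_fg_from_bg drop foreground ids from the background
#'   (default TRUE).
#' @param counting `"presence"` (default) or `"total"` (total occurrences
#'   compared by rate — Fisher is still computed on presence).
#' @return data.frame with one row per motif: `motif`, `fg_hits`, `fg_n`,
#'   `bg_hits`, `bg_n`, `odds_ratio`, `p_value` (and occurrence totals when
#'   `counting = "total"`).
#' @export
motif_enrichment <- function(seqs, motifs, foreground, background,
                             exclude_fg_from_bg = TRUE,
                             counting = c("presence", "total")) {
  counting <- match.arg(counting)
  if (inherits(motifs, "MotifSpec")) motifs <- list(motifs)
  dna <- as_dna_set(seqs)
  ids <- names(dna)
  missing_ids <- setdiff(c(foreground, background), ids)
  if (length(missing_ids))
    stop("no sequence for gene id(s): ",
         paste(head(missing_ids, 5), collapse = ", "))
  if (exclude_fg_from_bg) background <- setdiff(background, foreground)
  if (!length(foreground) || !length(background))
    stop("foreground and background must be non-empty")

  rows <- lapply(motifs, function(m) {
    occ <- motif_occurrences(dna, m)
    present <- occ > 0
    a <- sum(present[foreground]);  fg_n <- length(foreground)
    b <- sum(present[background]); bg_n <- length(background)
    tab <- matrix(c(a, fg_n - a, b, bg_n - b), nrow = 2)
    p <- fisher.test(tab)$p.value
    or <- if (any(tab == 0)) {
      ((a + 0.5) * (bg_n - b + 0.5)) / ((fg_n - a + 0.5) * (b + 0.5))
    } else {
      (a * (bg_n - b)) / ((fg_n - a) * b)
    }
    out <- data.frame(motif = m$name, fg_hits = a, fg_n = fg_n,
                      bg_hits = b, bg_n = bg_n,
                      odds_ratio = or, p_value = p,
                      stringsAsFactors = FALSE)
    if (counting == "total") {
      out$fg_occurrences <- sum(occ[foreground])
      out$bg_occurrences <- sum(occ[background])
    }
    out
  })
  do.call(rbind, rows)
}
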