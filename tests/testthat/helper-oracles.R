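# Fixture builders and independent brute-force oracles. Everything here is
# deliberately naive (per-read / per-base loops, full enumerations) and
# shares no code with the package internals it checks.

tiny_annotation <- function(chrom_len = 5000, n_spike = 1) {
  chroms <- data.frame(
    name = c("chr1", "chr2", if (n_spike) "spike_1"),
    length = c(chrom_len, chrom_len, if (n_spike) 2000))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(1000, 3500, 1200),
    tts = c(2500, 2000, 2900),
    plus1_dyad = c(1060, 3440, 1260),
    group = c("RP", "GR", "other"))
  genome_annotation(genes, chroms)
}

mk_contrast <- function(ids, fc, track = "other") {
  structure(data.frame(gene_id = ids, log2fc = fc,
                       treated_signal = NA_real_, vehicle_signal = NA_real_,
                       stringsAsFactors = FALSE),
            contrast_id = "t/v", track = track, pseudocount = 1,
            class = c("ContrastResult", "data.frame"))
}

make_read_set <- function(chrom, five_prime, strand, sample_id = "s",
                          sp_chrom = character(), sp_pos = numeric(),
                          sp_strand = character()) {
  target <- data.frame(chrom = chrom, five_prime = five_prime,
                       strand = strand, stringsAsFactors = FALSE)
  spikein <- data.frame(chrom = sp_chrom, five_prime = sp_pos,
                        strand = sp_strand, stringsAsFactors = FALSE)
  rs <- list(sample_id = sample_id, target = target, spikein = spikein,
             total_target = nrow(target), total_spikein = nrow(spikein),
             dropped = 0L)
  class(rs) <- "ReadSet"
  rs
}

random_read_set <- function(n, annotation, sample_id = "s") {
  tn <- annotation$chroms$name[annotation$chroms$species == "target"]
  ch <- sample(tn, n, replace = TRUE)
  len <- annotation$chroms$length[match(ch, annotation$chroms$name)]
  make_read_set(ch, floor(runif(n, 0, len)),
                sample(c("+", "-"), n, replace = TRUE), sample_id)
}

# per-read, per-base accumulation of the shift/extend transform
bf_coverage <- function(reads_df, shift, extend, chrom, chrom_len) {
  v <- numeric(chrom_len)
  for (i in seq_len(nrow(reads_df))) {
    if (reads_df$chrom[i] != chrom) next
    p <- if (reads_df$strand[i] == "+") reads_df$five_prime[i] + shift
         else reads_df$five_prime[i] - shift
    lo <- p - floor(extend / 2)
    hi <- p + ceiling(extend / 2) - 1
    for (b in lo:hi) if (b >= 0 && b < chrom_len) v[b + 1] <- v[b + 1] + 1
  }
  v
}

bf_midpoint_count <- function(reads_df, shift, chrom, start, end) {
  n <- 0
  for (i in seq_len(nrow(reads_df))) {
    if (reads_df$chrom[i] != chrom) next
    p <- if (reads_df$strand[i] == "+") reads_df$five_prime[i] + shift
         else reads_df$five_prime[i] - shift
    if (p >= start && p < end) n <- n + 1
  }
  n
}

# two-sided Fisher p as the sum of hypergeometric point probabilities of
# tables at least as unlikely as the observed one (fixed margins)
bf_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact Mann-Whitney two-sided p by enumerating every permutation of the
# pooled sample (factorial enumeration; use only for tiny n)
bf_mw_exact_p <- function(x, y) {
  pool <- c(x, y); n1 <- length(x); n <- length(pool)
  perms <- gtools_permutations(n)
  u_of <- function(xs, ys) {
    r <- rank(c(xs, ys))
    sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  mu <- n1 * (n - n1) / 2
  u_obs <- u_of(x, y)
  us <- apply(perms, 1, function(ix) u_of(pool[ix[1:n1]],
                                          pool[ix[(n1 + 1):n]]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# all permutations of 1..n (small n only), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(1:n, k)[sub], nrow(sub)))
  }))
}

# brute-force anchored extraction for metagene checks
bf_extract <- function(covvec, anchor, flank, strand) {
  w <- covvec[(anchor - flank + 1):(anchor + flank)]
  if (strand == "-") rev(w) else w
}
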