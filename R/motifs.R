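#' ZOOPS occurrence count of a k-mer
#'
#' Zero-or-one-occurrence-per-sequence counting: the number of sequences
#' containing at least one match of `kmer`, each sequence contributing at
#' most once however many times the motif occurs. Plain ACGT queries are
#' matched exactly; queries containing IUPAC degeneracy codes (R, Y, S, W,
#' K, M, B, D, H, V, N) are matched through character-class expansion.
#' Characters outside ACGT in the sequences are masked and never match.
#'
#' @param sequences Character vector of DNA sequences.
#' @param kmer Query motif (ACGT or IUPAC).
#' @return Integer count of sequences with at least one occurrence.
#' @export
zoops_count <- function(sequences, kmer) {
  if (!is.character(kmer) || length(kmer) != 1 || nchar(kmer) == 0) {
    stop("kmer must be a single non-empty string", call. = FALSE)
  }
  kmer <- toupper(kmer)
  seqs <- mask_non_acgt(toupper(sequences))
  if (grepl("^[ACGT]+$", kmer)) {
    sum(stringr::str_detect(seqs, stringr::fixed(kmer)))
  } else {
    pattern <- iupac_regex(kmer)
    sum(stringr::str_detect(seqs, pattern))
  }
}

iupac_codes <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_regex <- function(kmer) {
  chars <- strsplit(kmer, "")[[1]]
  bad <- setdiff(chars, names(iupac_codes))
  if (length(bad) > 0) {
    stop("unknown IUPAC code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  paste0(vapply(chars, function(ch) {
    ex <- iupac_codes[[ch]]
    if (nchar(ex) == 1) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

mask_non_acgt <- function(seqs) {
  gsub("[^ACGT]", "X", seqs)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of drawing at least `fg_with` motif-containing
#' sequences in `fg_n` draws from the pooled set of `fg_n + bg_n` sequences
#' of which `fg_with + bg_with` contain the motif.
#'
#' @param fg_with Foreground sequences containing the motif.
#' @param fg_n Foreground set size.
#' @param bg_with Background sequences containing the motif.
#' @param bg_n Background set size.
#' @return The p-value.
#' @export
hypergeometric_enrichment <- function(fg_with, fg_n, bg_with, bg_n) {
  if (fg_with < 0 || bg_with < 0 || fg_with > fg_n || bg_with > bg_n) {
    stop("inconsistent counts: need 0 <= fg_with <= fg_n and ",
         "0 <= bg_with <= bg_n", call. = FALSE)
  }
  stats::phyper(fg_with - 1, m = fg_with + bg_with,
                n = (fg_n + bg_n) - (fg_with + bg_with),
                k = fg_n, lower.tail = FALSE)
}

#' De novo k-mer motif discovery
#'
#' All `4^k` k-mers are scored by ZOOPS counting in foreground and
#' background with a hypergeometric enrichment test; p-values are BH
#' adjusted over the full `4^k` family and results ranked by p-value with a
#' lexicographic tie-break. When no background is supplied, one is generated
#' per foreground sequence from a first-order Markov chain fitted to the
#' foreground (preserving dinucleotide composition in expectation).
#'
#' @param fg Character vector of foreground (peak) sequences.
#' @param bg Optional character vector of background sequences.
#' @param k Motif length (at most 12).
#' @param top Number of top motifs to return.
#' @return A tibble of class `motif_result`: `kmer`, `fg_with`, `fg_n`,
#'   `bg_with`, `bg_n`, `pvalue`, `qvalue`, ranked by significance.
#' @export
discover_motifs <- function(fg, bg = NULL, k = 8, top = 10) {
  if (length(fg) == 0) stop("empty foreground", call. = FALSE)
  if (k > 12) stop("k > 12 rejected (enumeration guard)", call. = FALSE)
  stopifnot(k >= 1)
  fg <- toupper(fg)
  if (is.null(bg)) bg <- markov_background(fg)
  if (length(bg) == 0) stop("empty background", call. = FALSE)
  bg <- toupper(bg)

  fg_tab <- zoops_table(fg, k)
  bg_tab <- zoops_table(bg, k)
  kmers <- sort(union(names(fg_tab), names(bg_tab)))
  fg_with <- unname(ifelse(is.na(fg_tab[kmers]), 0L, fg_tab[kmers]))
  bg_with <- unname(ifelse(is.na(bg_tab[kmers]), 0L, bg_tab[kmers]))
  p <- mapply(hypergeometric_enrichment, fg_with, length(fg), bg_with,
              length(bg))
  q <- stats::p.adjust(p, method = "BH", n = 4^k)
  out <- tibble::tibble(
    kmer = kmers, fg_with = as.integer(fg_with), fg_n = length(fg),
    bg_with = as.integer(bg_with), bg_n = length(bg),
    pvalue = p, qvalue = q
  ) |>
    dplyr::arrange(.data$pvalue, .data$kmer) |>
    utils::head(top)
  class(out) <- c("motif_result", class(out))
  out
}

# per-sequence unique k-mers, tabulated over the sequence set (ZOOPS)
zoops_table <- function(seqs, k) {
  seqs <- mask_non_acgt(seqs)
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, seq_len(n - k + 1), seq.int(k, n))
    unique(km[!grepl("X", km, fixed = TRUE)])
  })
  tab <- table(unlist(per_seq, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' First-order Markov background sequences
#'
#' Generates one background sequence per foreground sequence (same lengths)
#' from a first-order Markov chain fitted to the pooled foreground,
#' preserving mono- and dinucleotide composition in expectation.
#'
#' @param fg Character vector of foreground sequences.
#' @return Character vector of background sequences.
#' @export
markov_background <- function(fg) {
  seqs <- mask_non_acgt(toupper(fg))
  chars <- strsplit(paste(seqs, collapse = "X"), "")[[1]]
  bases <- c("A", "C", "G", "T")
  from <- chars[-length(chars)]
  to <- chars[-1]
  keep <- from %in% bases & to %in% bases
  trans <- table(factor(from[keep], bases), factor(to[keep], bases)) + 1
  trans <- sweep(as.matrix(trans), 1, rowSums(trans), "/")
  start <- table(factor(chars[chars %in% bases], bases)) + 1
  start <- as.numeric(start / sum(start))
  vapply(nchar(seqs), function(len) {
    if (len == 0) return("")
    out <- character(len)
    out[1] <- sample(bases, 1, prob = start)
    for (i in seq_len(len - 1)) {
      out[i + 1] <- sample(bases, 1, prob = trans[out[i], ])
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Random DNA sequences and motif planting
#'
#' Helpers for constructing synthetic motif-discovery inputs:
#' `random_sequences()` draws uniform ACGT sequences; `plant_motif()`
#' inserts a motif at a random position into a given fraction of sequences.
#'
#' @param n Number of sequences.
#' @param len Sequence length in nt.
#' @return `random_sequences()`: character vector of sequences.
#' @export
random_sequences <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' @rdname random_sequences
#' @param sequences Character vector to plant into.
#' @param motif Motif string (ACGT).
#' @param fraction Fraction of sequences receiving one motif insertion.
#' @return `plant_motif()`: the sequences with the motif planted.
#' @export
plant_motif <- function(sequences, motif, fraction = 0.8) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(sequences)
  pick <- seq_len(floor(fraction * n))
  for (i in pick) {
    s <- sequences[i]
    maxpos <- nchar(s) - nchar(motif) + 1
    if (maxpos < 1) next
    pos <- sample.int(maxpos, 1)
    substr(s, pos, pos + nchar(motif) - 1) <- motif
    sequences[i] <- s
  }
  sequences
}
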