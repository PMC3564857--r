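#' Generate a synthetic pair of homologous test sequences
#'
#' Stand-in for a naturally diverged homolog pair (such as two
#' beta-lactamase gene variants with ~5% divergence): `seq_b` is `seq_a`
#' with random substitutions at rate `divergence` and, optionally, 1-bp
#' indels at rate `indel_rate`.
#'
#' @param length Sequence length in bp.
#' @param divergence Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base probability of a 1-bp indel (default 0).
#' @param seed Optional RNG seed.
#' @return A list of class `arm_pair` with `seq_a`, `seq_b`, labels, and
#'   `diff_positions`, the realized substitution positions in `seq_a`
#'   coordinates (indels excluded).
#' @examples
#' ap <- make_synthetic_homologs(800, 0.05, seed = 7)
#' length(ap$diff_positions)
#' @export
make_synthetic_homologs <- function(length, divergence, indel_rate = 0,
                                    seed = NULL) {
  stopifnot(length >= 1, divergence >= 0, divergence < 1,
            indel_rate >= 0, indel_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, length, replace = TRUE)
  b <- a
  subs <- which(runif(length) < divergence)
  for (i in subs) b[i] <- sample(setdiff(bases, a[i]), 1)
  if (indel_rate > 0) {
    ind <- which(runif(length) < indel_rate)
    # apply from the right so earlier coordinates stay valid
    for (i in rev(ind)) {
      if (runif(1) < 0.5) {                        # insertion in b
        b <- append(b, sample(bases, 1), after = i)
      } else {                                     # deletion from b
        b <- b[-min(i, base::length(b))]
      }
    }
  }
  structure(list(seq_a = paste(a, collapse = ""),
                 seq_b = paste(b, collapse = ""),
                 label_a = "synthetic-arm-a", label_b = "synthetic-arm-b",
                 diff_positions = subs),
            class = "arm_pair")
}

#' Pair of homologous arm sequences
#'
#' @param seq_a,seq_b Nucleotide strings (ACGT; lowercase accepted).
#' @param label_a,label_b Free-text labels.
#' @return An object of class `arm_pair`.
#' @export
arm_pair <- function(seq_a, seq_b, label_a = "arm-a", label_b = "arm-b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    if (grepl("[^ACGT]", s)) {
      stop("sequence contains non-ACGT characters", call. = FALSE)
    }
  }
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 label_a = label_a, label_b = label_b),
            class = "arm_pair")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# The construct folds back on itself, so arm-a base X opposite arm-b base Y
# forms the heteroduplex mismatches X/comp(Y) and comp(X)/Y, one on each
# recombined arm. Each mismatch is written alphabetically and the two are
# joined with "+", e.g. an A<->C substitution gives "A/G+C/T".
mismatch_pair_label <- function(x, y) {
  m1 <- sort(c(x, unname(comp_base[y])))
  m2 <- sort(c(unname(comp_base[x]), y))
  pairs <- sort(c(paste(m1, collapse = "/"), paste(m2, collapse = "/")))
  paste(pairs, collapse = "+")
}

#' Find the sequence differences between the two arms
#'
#' Compares the two homologous test sequences and returns one row per
#' difference: position-wise for equal-length inputs, after a global
#' (Needleman-Wunsch) alignment otherwise. Each substitution implies two
#' heteroduplex mismatches upon recombination (one on each recombined arm),
#' reported in `mismatch_pair`; a 1-bp indel implies a base bulge on each
#' arm and is reported as a single insertion/deletion locus.
#'
#' @param arms An [arm_pair()].
#' @param offset_to_center Bases between the construct's center of symmetry
#'   and the start of the test segment: `base_index = offset_to_center +
#'   position` within the segment (1-based).
#' @param hr_dna Helical repeat used for the expected blockage rotations.
#' @return A `data.frame` of class `mismatch_table` with columns
#'   `base_index`, `kind` (substitution/insertion/deletion),
#'   `mismatch_pair`, and `expected_rotation` (turns, negative).
#' @examples
#' ap <- arm_pair("ACGTACGT", "ACGAACGT")
#' find_differences(ap, offset_to_center = 2000)
#' @export
find_differences <- function(arms, offset_to_center = 0, hr_dna = 10.45) {
  stopifnot(inherits(arms, "arm_pair"))
  a <- toupper(arms$seq_a); b <- toupper(arms$seq_b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)

  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    pos <- which(av != bv)
    tab <- data.frame(
      base_index = offset_to_center + pos,
      kind = rep("substitution", length(pos)),
      mismatch_pair = vapply(pos, function(i)
        mismatch_pair_label(av[i], bv[i]), character(1)),
      stringsAsFactors = FALSE)
  } else {
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         gapOpening = 10, gapExtension = 4)
    pid <- Biostrings::pid(aln)
    if (pid < 80) {
      warning(sprintf(
        "alignment identity %.1f%% < 80%%: construct implausible", pid))
    }
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    pos_a <- cumsum(pa != "-")    # coordinate in seq_a at each column
    rows <- list()
    for (k in seq_along(pa)) {
      if (pa[k] == pb[k]) next
      if (pa[k] == "-") {
        rows[[length(rows) + 1L]] <- data.frame(
          base_index = offset_to_center + pos_a[k],
          kind = "insertion",
          mismatch_pair = paste0(pb[k], "-bulge+",
                                 comp_base[[pb[k]]], "-bulge"),
          stringsAsFactors = FALSE)
      } else if (pb[k] == "-") {
        rows[[length(rows) + 1L]] <- data.frame(
          base_index = offset_to_center + pos_a[k],
          kind = "deletion",
          mismatch_pair = paste0(pa[k], "-bulge+",
                                 comp_base[[pa[k]]], "-bulge"),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          base_index = offset_to_center + pos_a[k],
          kind = "substitution",
          mismatch_pair = mismatch_pair_label(pa[k], pb[k]),
          stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(base_index = numeric(0), kind = character(0),
                 mismatch_pair = character(0), stringsAsFactors = FALSE)
  }
  tab <- tab[order(tab$base_index), , drop = FALSE]
  rownames(tab) <- NULL
  expected_rotations(structure(tab, class = c("mismatch_table",
                                              "data.frame")),
                     hr_dna = hr_dna)
}

#' Expected blockage rotations from mismatch base indices
#'
#' A mismatch `b` bases from the construct center blocks when the junction
#' has advanced there, i.e. after `2 b / hr_dna` bead turns of unwinding;
#' the expected blockage rotation is therefore `-2 * base_index / hr_dna`
#' (negative: the junction is extruded by unwinding).
#'
#' @param table A `mismatch_table` (or data frame with a `base_index`
#'   column).
#' @param hr_dna Helical repeat (bp/turn, default 10.45).
#' @return The table with the `expected_rotation` column (re)filled.
#' @examples
#' tab <- data.frame(base_index = 2386)
#' expected_rotations(tab)$expected_rotation   # about -456.7 turns
#' @export
expected_rotations <- function(table, hr_dna = 10.45) {
  stopifnot(!is.null(table$base_index), hr_dna > 0)
  table$expected_rotation <- -2 * table$base_index / hr_dna
  if (!inherits(table, "mismatch_table")) {
    class(table) <- c("mismatch_table", class(table))
  }
  table
}

#' @export
print.mismatch_table <- function(x, ...) {
  cat(sprintf("Mismatch table: %d loci\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
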