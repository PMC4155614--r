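#' Conservation profile for synthetic alignments
#'
#' Describes the generative model for one synthetic sample: every column has a
#' modal residue drawn with a stated probability, with the remaining mass
#' spread over a background distribution; optionally, a fraction of the
#' sequences forms a subgroup whose modal path is shifted by a fixed column
#' offset from a start column onward (emulating an apparent single-residue
#' insertion/deletion that puts a subfamily "out of phase" with the rest).
#' Columns are sampled independently — enough to exercise every diagram
#' feature, but not a phylogenetically realistic substitution model.
#'
#' @param n_columns Number of alignment columns.
#' @param modal_residues Character vector (length `n_columns`) or single
#'   string: the modal residue per column.
#' @param modal_prob Probability of the modal residue at each column; scalar
#'   or vector of length `n_columns`. Must lie in `[1/alphabet size, 1]`.
#' @param alphabet Residue alphabet to sample from. Default: the 20 standard
#'   amino acids.
#' @param background Either `"uniform"` (equal mass over the non-modal
#'   residues; default) or a named probability vector over the alphabet.
#' @param subgroup_fraction Fraction of sequences in the shifted subgroup,
#'   in `[0, 1)`. Default 0.
#' @param subgroup_offset Signed column shift of the subgroup's modal path;
#'   `|offset| < n_columns`.
#' @param subgroup_start First (1-based) column of the shifted region.
#' @return An object of class `conservation_profile`.
#' @export
conservation_profile <- function(n_columns = 40,
                                 modal_residues,
                                 modal_prob = 0.85,
                                 alphabet = default_protein_scheme()$alphabet,
                                 background = "uniform",
                                 subgroup_fraction = 0,
                                 subgroup_offset = 0,
                                 subgroup_start = 1) {
  if (is.character(modal_residues) && length(modal_residues) == 1 &&
      nchar(modal_residues) > 1) {
    modal_residues <- strsplit(modal_residues, "")[[1]]
  }
  modal_residues <- toupper(modal_residues)
  if (length(modal_residues) != n_columns) {
    sdd_error("modal_residues must cover every column", "sdd_bad_config")
  }
  if (!all(modal_residues %in% alphabet)) {
    sdd_error("modal residues must be drawn from the alphabet", "sdd_bad_config")
  }
  modal_prob <- rep_len(modal_prob, n_columns)
  if (any(modal_prob < 1 / length(alphabet)) || any(modal_prob > 1)) {
    sdd_error(sprintf("modal_prob must lie in [1/%d, 1]", length(alphabet)),
              "sdd_bad_config")
  }
  if (subgroup_fraction < 0 || subgroup_fraction >= 1) {
    sdd_error("subgroup_fraction must lie in [0, 1)", "sdd_bad_config")
  }
  if (abs(subgroup_offset) >= n_columns) {
    sdd_error("|subgroup_offset| must be smaller than n_columns",
              "sdd_bad_config")
  }
  structure(
    list(n_columns = as.integer(n_columns), modal_residues = modal_residues,
         modal_prob = modal_prob, alphabet = alphabet, background = background,
         subgroup_fraction = subgroup_fraction,
         subgroup_offset = as.integer(subgroup_offset),
         subgroup_start = as.integer(subgroup_start)),
    class = "conservation_profile"
  )
}

# Modal path of the shifted subgroup: within the shifted window
# [subgroup_start, n_columns], row indices are rotated by the offset
# (circular within the window); columns before the window are unchanged.
shifted_modal_path <- function(profile) {
  m <- profile$modal_residues
  s <- profile$subgroup_start
  L <- profile$n_columns
  if (profile$subgroup_offset == 0 || s > L) return(m)
  win <- s:L
  src <- s + (win - s - profile$subgroup_offset) %% length(win)
  m[win] <- m[src]
  m
}

#' Generate a synthetic alignment group
#'
#' Samples `n_sequences` aligned sequences from a [conservation_profile()]:
#' each column independently carries the (possibly subgroup-shifted) modal
#' residue with its stated probability and a background residue otherwise.
#' The first `round(subgroup_fraction * n_sequences)` sequences form the
#' shifted subgroup. A fixed seed gives identical output.
#'
#' @param profile A [conservation_profile()].
#' @param n_sequences Number of sequences to draw (>= 1).
#' @param label Group label.
#' @param color Optional display color.
#' @param seed Integer seed for reproducibility; `NULL` uses (and advances)
#'   the session RNG.
#' @return An [alignment_group()].
#' @examples
#' pr <- conservation_profile(5, "PAKLG", modal_prob = 1)
#' g <- generate_group(pr, 3, "demo", seed = 1)
#' unique(g$sequences)  # "PAKLG"
#' @export
generate_group <- function(profile, n_sequences, label, color = NULL,
                           seed = NULL) {
  stopifnot(inherits(profile, "conservation_profile"), n_sequences >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- profile$n_columns
  alpha <- profile$alphabet
  n_sub <- round(profile$subgroup_fraction * n_sequences)
  paths <- list(main = profile$modal_residues,
                sub = shifted_modal_path(profile))
  member <- c(rep("sub", n_sub), rep("main", n_sequences - n_sub))

  m <- matrix("", nrow = n_sequences, ncol = L)
  for (i in seq_len(L)) {
    p <- profile$modal_prob[i]
    for (who in unique(member)) {
      rows <- which(member == who)
      modal <- paths[[who]][i]
      take_modal <- stats::runif(length(rows)) < p
      m[rows[take_modal], i] <- modal
      n_bg <- sum(!take_modal)
      if (n_bg > 0) {
        if (identical(profile$background, "uniform")) {
          bg_pool <- setdiff(alpha, modal)
          m[rows[!take_modal], i] <- sample(bg_pool, n_bg, replace = TRUE)
        } else {
          w <- profile$background[alpha]
          w[is.na(w)] <- 0
          w[alpha == modal] <- 0
          m[rows[!take_modal], i] <- sample(alpha, n_bg, replace = TRUE,
                                            prob = w)
        }
      }
    }
  }
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- sprintf("%s_%04d", label, seq_len(n_sequences))
  alignment_group(seqs, label = label, color = color)
}

# Fixed 40-column modal string for the bundled demo fixture: P at column 5 is
# followed by A at column 6, and no two adjacent columns share a modal
# residue (so the offset subgroup path is distinguishable from the main one).
AKL_MODAL_STRING <- "MKLTPAVRESDLGWKNIQYCFHMTEDSRAVLGNKIWQEYF"

#' Synthetic two-sample fixture with a planted subgroup
#'
#' Generates the bundled demonstration dataset: two samples of aligned
#' 40-column protein sequences emulating a two-subfamily comparison (such as
#' the adenylate kinase lid domain of Gram-negative vs Gram-positive
#' bacteria). Both samples share one modal path with per-column conservation
#' 0.85 — including Proline at position 5 followed by Alanine at position 6 —
#' and the second sample additionally carries a 20% subgroup whose modal path
#' is shifted by +1 column from position 19 onward, producing the
#' "out-of-phase" parallel path a comparative diagram should reveal.
#'
#' @param n_sequences Sequences per sample. Default 500.
#' @param seed Integer seed. Default 20130613 (the committed fixture files
#'   under `inst/extdata` were written with this default).
#' @return Named list of two [alignment_group()]s: `gram_negative`,
#'   `gram_positive`.
#' @export
synthetic_akl_groups <- function(n_sequences = 500, seed = 20130613) {
  base <- conservation_profile(
    n_columns = 40, modal_residues = AKL_MODAL_STRING, modal_prob = 0.85
  )
  with_sub <- conservation_profile(
    n_columns = 40, modal_residues = AKL_MODAL_STRING, modal_prob = 0.85,
    subgroup_fraction = 0.2, subgroup_offset = 1, subgroup_start = 19
  )
  list(
    gram_negative = generate_group(base, n_sequences, "gram_negative",
                                   seed = seed),
    gram_positive = generate_group(with_sub, n_sequences, "gram_positive",
                                   seed = seed + 1)
  )
}
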