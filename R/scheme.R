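#' Residue alphabet schemes
#'
#' An `alphabet_scheme` defines the y-axis of a Sequence Diversity Diagram: an
#' ordered partition of the residue alphabet into functional groups. Every
#' residue belongs to exactly one group; the concatenated group order defines
#' the total vertical order of rows. Ambiguity symbols, when declared, map to
#' a dedicated `"other"` row, and the gap symbol `"-"` gets its own bottom row
#' unless `gap_row_policy = "excluded"`.
#'
#' @param groups Named list of character vectors; each element is one ordered
#'   functional group of single-character residue symbols.
#' @param gap_row_policy Either `"own_row"` (gaps occupy a visible bottom row;
#'   the default, so column counts always sum to the number of sequences) or
#'   `"excluded"` (gap characters are dropped from frequency tables).
#' @param ambiguity_symbols Character vector of accepted ambiguity codes
#'   (e.g. `"X"`), all mapped to one `"other"` row after the named groups.
#' @param aliases Named character vector mapping input symbols to the row that
#'   counts them (used e.g. to merge U into the T row for mixed DNA/RNA input).
#' @return An object of class `alphabet_scheme` with fields `alphabet`,
#'   `groups`, `gap_row_policy`, `ambiguity_symbols`, `aliases`.
#' @examples
#' sch <- alphabet_scheme(list(purine = c("A", "G"), pyrimidine = c("C", "T")))
#' scheme_rows(sch)
#' @export
alphabet_scheme <- function(groups, gap_row_policy = c("own_row", "excluded"),
                            ambiguity_symbols = character(),
                            aliases = character()) {
  gap_row_policy <- match.arg(gap_row_policy)
  if (!is.list(groups) || length(groups) == 0 || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    sdd_error("'groups' must be a non-empty named list of residue vectors",
              "sdd_bad_config")
  }
  groups <- lapply(groups, function(g) toupper(as.character(g)))
  ambiguity_symbols <- toupper(as.character(ambiguity_symbols))
  residues <- unlist(groups, use.names = FALSE)
  if (any(nchar(residues) != 1L)) {
    sdd_error("residue symbols must be single characters", "sdd_bad_config")
  }
  dup <- unique(residues[duplicated(residues)])
  if (length(dup) > 0) {
    sdd_error(sprintf("ambiguous grouping: residue(s) %s assigned to two groups",
                      paste(dup, collapse = ", ")), "sdd_bad_config")
  }
  if ("-" %in% c(residues, ambiguity_symbols)) {
    sdd_error("the gap symbol '-' cannot be a member of a residue group",
              "sdd_bad_config")
  }
  if (length(ambiguity_symbols) > 0 && any(ambiguity_symbols %in% residues)) {
    sdd_error("ambiguity symbols must not overlap the grouped alphabet",
              "sdd_bad_config")
  }
  if (length(aliases) > 0) {
    if (is.null(names(aliases)) || any(!toupper(aliases) %in% residues)) {
      sdd_error("aliases must be a named vector mapping onto grouped residues",
                "sdd_bad_config")
    }
    aliases <- stats::setNames(toupper(aliases), toupper(names(aliases)))
  }
  structure(
    list(
      alphabet = residues,
      groups = groups,
      gap_row_policy = gap_row_policy,
      ambiguity_symbols = ambiguity_symbols,
      aliases = aliases
    ),
    class = "alphabet_scheme"
  )
}

#' @export
print.alphabet_scheme <- function(x, ...) {
  cat(sprintf("<alphabet_scheme: %d residues in %d groups; gaps: %s>\n",
              length(x$alphabet), length(x$groups), x$gap_row_policy))
  for (g in names(x$groups)) {
    cat(sprintf("  %-12s %s\n", g, paste(x$groups[[g]], collapse = " ")))
  }
  if (length(x$ambiguity_symbols)) {
    cat(sprintf("  %-12s %s\n", "other", paste(x$ambiguity_symbols, collapse = " ")))
  }
  invisible(x)
}

#' Row order of a scheme
#'
#' Returns the full y-axis row table for a scheme, top to bottom: the grouped
#' residues in declaration order, then the `"other"` row (if ambiguity symbols
#' are declared), then the gap row (if `gap_row_policy == "own_row"`).
#'
#' @param scheme An [alphabet_scheme()].
#' @return A data frame with columns `residue` and `group`.
#' @export
scheme_rows <- function(scheme) {
  stopifnot(inherits(scheme, "alphabet_scheme"))
  rows <- data.frame(
    residue = unlist(scheme$groups, use.names = FALSE),
    group = rep(names(scheme$groups), lengths(scheme$groups)),
    stringsAsFactors = FALSE
  )
  if (length(scheme$ambiguity_symbols) > 0) {
    rows <- rbind(rows, data.frame(residue = "other", group = "other"))
  }
  if (scheme$gap_row_policy == "own_row") {
    rows <- rbind(rows, data.frame(residue = "-", group = "gap"))
  }
  rows
}

# Map raw (uppercased) characters to the row residue that counts them:
# aliases collapse first, ambiguity codes collapse to "other".
scheme_row_of <- function(scheme, chars) {
  if (length(scheme$aliases) > 0) {
    hit <- chars %in% names(scheme$aliases)
    chars[hit] <- scheme$aliases[chars[hit]]
  }
  chars[chars %in% scheme$ambiguity_symbols] <- "other"
  chars
}

# Characters legal in input sequences under this scheme (before aliasing).
scheme_legal_chars <- function(scheme) {
  c(scheme$alphabet, scheme$ambiguity_symbols, names(scheme$aliases), "-")
}

#' Default protein scheme
#'
#' The 20 standard amino acids partitioned by side-chain structure and
#' chemistry: aliphatic/hydrophobic (A V L I M), aromatic (F W Y), polar
#' uncharged (S T N Q), positively charged (K R H), negatively charged (D E),
#' and special (C G P). This is one standard physicochemical classification;
#' the grouping and its order are fully configurable via [load_config()].
#'
#' @param gap_row_policy See [alphabet_scheme()].
#' @param ambiguity If `TRUE`, accept the protein ambiguity codes X, B, Z, J
#'   and map them to an `"other"` row. Default `FALSE`.
#' @return An [alphabet_scheme()].
#' @examples
#' default_protein_scheme()
#' @export
default_protein_scheme <- function(gap_row_policy = c("own_row", "excluded"),
                                   ambiguity = FALSE) {
  alphabet_scheme(
    groups = list(
      aliphatic = c("A", "V", "L", "I", "M"),
      aromatic  = c("F", "W", "Y"),
      polar     = c("S", "T", "N", "Q"),
      positive  = c("K", "R", "H"),
      negative  = c("D", "E"),
      special   = c("C", "G", "P")
    ),
    gap_row_policy = match.arg(gap_row_policy),
    ambiguity_symbols = if (ambiguity) c("X", "B", "Z", "J") else character()
  )
}

#' Default nucleotide scheme
#'
#' Bases grouped by ring chemistry: purines (A, G) and pyrimidines (C, T, U).
#' By default both T and U are accepted, each on its own row; `type = "dna"`
#' or `"rna"` restricts the alphabet, and `merge_tu = TRUE` makes U an alias
#' of the T row so mixed DNA/RNA input shares one pyrimidine row.
#'
#' @param type `"both"` (default), `"dna"` (A C G T) or `"rna"` (A C G U).
#' @param merge_tu Count U on the T row (only meaningful for `type = "both"`).
#' @param gap_row_policy See [alphabet_scheme()].
#' @param ambiguity If `TRUE`, accept IUPAC nucleotide ambiguity codes
#'   (R Y S W K M B D H V N) on an `"other"` row.
#' @return An [alphabet_scheme()].
#' @export
default_nucleotide_scheme <- function(type = c("both", "dna", "rna"),
                                      merge_tu = FALSE,
                                      gap_row_policy = c("own_row", "excluded"),
                                      ambiguity = FALSE) {
  type <- match.arg(type)
  pyr <- switch(type, both = c("C", "T", "U"), dna = c("C", "T"),
                rna = c("C", "U"))
  aliases <- character()
  if (merge_tu && type == "both") {
    pyr <- c("C", "T")
    aliases <- c(U = "T")
  }
  alphabet_scheme(
    groups = list(purine = c("A", "G"), pyrimidine = pyr),
    gap_row_policy = match.arg(gap_row_policy),
    ambiguity_symbols = if (ambiguity) {
      setdiff(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"), pyr)
    } else character(),
    aliases = aliases
  )
}

#' Diagram configuration
#'
#' Holds every tunable parameter of the diagram. All values have defaults; the
#' same structure is produced by [load_config()] from a YAML file.
#'
#' @param filter_threshold Pair-frequency filter threshold in `[0, 1]`; pairs
#'   with relative frequency strictly below it are removed. Default `0.01`
#'   (one percent).
#' @param group_colors Named character vector mapping group labels to colors
#'   (`"#RRGGBB"` or `"#RRGGBBAA"`), or `NULL` for the built-in
#'   semi-transparent palette (red, blue, ... at alpha 0.5) so two overlaid
#'   samples blend optically (red + blue reads as purple).
#' @param column_spacing Horizontal distance between alignment positions, in
#'   abstract figure units (points when rendered). Default 40.
#' @param row_spacing Vertical distance between residue rows within one
#'   functional group. Default 14.
#' @param group_gap Extra vertical gap between functional groups (the visual
#'   enhancement that makes groups readable). Must be > 0. Default 12.
#' @param max_ribbon_weight Stroke width (same units) of a ribbon carrying
#'   relative frequency 1.0; all ribbon widths scale linearly from it.
#'   Must be > 0. Default 10.
#' @param masked_positions Integer vector of 1-based alignment positions whose
#'   ribbons are suppressed (axis labels are kept).
#' @param output_format One of `"svg"`, `"png"`, `"pdf"`.
#' @param denominator_policy `"per_group"` (pair frequencies are relative to
#'   each sample's own sequence count; default) or `"combined"` (relative to
#'   the total across samples).
#' @param include_gap_pairs Count transitions in which either residue is a gap
#'   (default `TRUE`; they flow through the gap row).
#' @param dot_as_gap Treat `"."` in input FASTA as the gap symbol. Default
#'   `FALSE` (a dot is rejected as an unknown residue).
#' @return An object of class `diagram_config`.
#' @export
diagram_config <- function(filter_threshold = 0.01,
                           group_colors = NULL,
                           column_spacing = 40,
                           row_spacing = 14,
                           group_gap = 12,
                           max_ribbon_weight = 10,
                           masked_positions = integer(),
                           output_format = c("svg", "png", "pdf"),
                           denominator_policy = c("per_group", "combined"),
                           include_gap_pairs = TRUE,
                           dot_as_gap = FALSE) {
  output_format <- match.arg(output_format)
  denominator_policy <- match.arg(denominator_policy)
  if (!is.numeric(filter_threshold) || length(filter_threshold) != 1 ||
      is.na(filter_threshold) || filter_threshold < 0 || filter_threshold > 1) {
    sdd_error("filter_threshold must be a single number in [0, 1]",
              "sdd_bad_config")
  }
  if (!is.numeric(group_gap) || group_gap <= 0) {
    sdd_error("group_gap must be > 0", "sdd_bad_config")
  }
  if (!is.numeric(max_ribbon_weight) || max_ribbon_weight <= 0) {
    sdd_error("max_ribbon_weight must be > 0", "sdd_bad_config")
  }
  if (!is.numeric(column_spacing) || column_spacing <= 0 ||
      !is.numeric(row_spacing) || row_spacing <= 0) {
    sdd_error("column_spacing and row_spacing must be > 0", "sdd_bad_config")
  }
  masked_positions <- sort(unique(as.integer(masked_positions)))
  if (length(masked_positions) > 0 && any(masked_positions < 1)) {
    sdd_error("masked_positions are 1-based and must be >= 1", "sdd_bad_config")
  }
  structure(
    list(
      filter_threshold = filter_threshold,
      group_colors = group_colors,
      column_spacing = as.numeric(column_spacing),
      row_spacing = as.numeric(row_spacing),
      group_gap = as.numeric(group_gap),
      max_ribbon_weight = as.numeric(max_ribbon_weight),
      masked_positions = masked_positions,
      output_format = output_format,
      denominator_policy = denominator_policy,
      include_gap_pairs = isTRUE(include_gap_pairs),
      dot_as_gap = isTRUE(dot_as_gap)
    ),
    class = "diagram_config"
  )
}

#' @export
print.diagram_config <- function(x, ...) {
  cat("<diagram_config>\n")
  cat(sprintf("  filter_threshold:   %g\n", x$filter_threshold))
  cat(sprintf("  denominator_policy: %s\n", x$denominator_policy))
  cat(sprintf("  geometry: column_spacing=%g row_spacing=%g group_gap=%g max_ribbon_weight=%g\n",
              x$column_spacing, x$row_spacing, x$group_gap, x$max_ribbon_weight))
  if (length(x$masked_positions)) {
    cat(sprintf("  masked positions: %s\n", paste(x$masked_positions, collapse = ", ")))
  }
  invisible(x)
}

# Built-in semi-transparent sample palette; alpha 0.5 so overlap blends.
default_group_colors <- function(n) {
  base <- c("#D62728", "#1F77B4", "#2CA02C", "#FF7F0E", "#9467BD",
            "#8C564B", "#17BECF", "#BCBD22")
  if (n > length(base)) base <- rep_len(base, n)
  paste0(base[seq_len(n)], "80")
}

#' Load a scheme and diagram configuration from a YAML file
#'
#' The configuration file is a flat, human-editable YAML document. Every key
#' is optional; omitted keys take the documented defaults (protein scheme,
#' filter threshold 0.01). Recognized top-level keys:
#' \describe{
#'   \item{`alphabet`}{`"protein"` (default) or `"nucleotide"`.}
#'   \item{`groups`}{Map of group label to a residue string (e.g. `"AVLIM"`)
#'     or list of residues; overrides the built-in grouping. Declaration order
#'     defines the y-axis order.}
#'   \item{`gap_row_policy`}{`"own_row"` or `"excluded"`.}
#'   \item{`ambiguity`}{`true` to accept standard ambiguity codes, or an
#'     explicit list of symbols.}
#'   \item{`merge_tu`}{Nucleotide only: count U on the T row.}
#'   \item{`filter`}{Map with key `threshold` (fraction in `[0, 1]`).}
#'   \item{`colors`}{Map of sample label to `#RRGGBB[AA]` color.}
#'   \item{`geometry`}{Map with keys `column_spacing`, `row_spacing`,
#'     `group_gap`, `max_ribbon_weight`.}
#'   \item{`mask`}{List of 1-based positions to mask.}
#'   \item{`output`}{Map with key `format` (`svg`, `png`, `pdf`).}
#'   \item{`denominator`}{`"per_group"` or `"combined"`.}
#'   \item{`gap_pairs`}{`true`/`false`: count transitions involving gaps.}
#'   \item{`dot_as_gap`}{`true` to map `"."` to `"-"` on input.}
#' }
#' Unknown keys produce a warning, not an error. A commented template ships at
#' `system.file("extdata", "seqdiv_config_template.yml", package = "seqdivdiag")`.
#'
#' @param path Path to the YAML configuration file.
#' @return A list with elements `scheme` ([alphabet_scheme()]) and `config`
#'   ([diagram_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    sdd_error(sprintf("config file not found: %s", path), "sdd_missing_file")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    sdd_error(sprintf("cannot parse config file %s: %s", path,
                      conditionMessage(e)), "sdd_bad_config")
  })
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    sdd_error("config file must contain a YAML mapping", "sdd_bad_config")
  }
  known <- c("alphabet", "groups", "gap_row_policy", "ambiguity", "merge_tu",
             "aliases", "filter", "colors", "geometry", "mask", "output",
             "denominator", "gap_pairs", "dot_as_gap")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }

  gap_policy <- raw$gap_row_policy %||% "own_row"
  amb <- raw$ambiguity %||% FALSE

  if (!is.null(raw$groups)) {
    groups <- lapply(raw$groups, function(g) {
      if (is.character(g) && length(g) == 1 && nchar(g) > 1) {
        strsplit(g, "")[[1]]
      } else {
        as.character(g)
      }
    })
    scheme <- alphabet_scheme(
      groups, gap_row_policy = gap_policy,
      ambiguity_symbols = if (is.logical(amb)) character()
        else toupper(as.character(unlist(amb))),
      aliases = unlist(raw$aliases) %||% character()
    )
  } else {
    kind <- raw$alphabet %||% "protein"
    scheme <- switch(kind,
      protein = default_protein_scheme(gap_row_policy = gap_policy,
                                       ambiguity = isTRUE(amb)),
      nucleotide = default_nucleotide_scheme(
        merge_tu = isTRUE(raw$merge_tu),
        gap_row_policy = gap_policy,
        ambiguity = isTRUE(amb)
      ),
      sdd_error(sprintf("unknown alphabet '%s' (use 'protein' or 'nucleotide')",
                        kind), "sdd_bad_config")
    )
    if (!is.logical(amb) && length(amb) > 0) {
      scheme$ambiguity_symbols <- toupper(as.character(amb))
    }
  }

  geom <- raw$geometry %||% list()
  colors <- raw$colors
  if (!is.null(colors)) colors <- unlist(colors)
  config <- diagram_config(
    filter_threshold = raw$filter$threshold %||% 0.01,
    group_colors = colors,
    column_spacing = geom$column_spacing %||% 40,
    row_spacing = geom$row_spacing %||% 14,
    group_gap = geom$group_gap %||% 12,
    max_ribbon_weight = geom$max_ribbon_weight %||% 10,
    masked_positions = unlist(raw$mask) %||% integer(),
    output_format = raw$output$format %||% "svg",
    denominator_policy = raw$denominator %||% "per_group",
    include_gap_pairs = raw$gap_pairs %||% TRUE,
    dot_as_gap = raw$dot_as_gap %||% FALSE
  )
  list(scheme = scheme, config = config)
}

#' Write a scheme and configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(scheme, config, path))`
#' reproduces both objects.
#'
#' @param scheme An [alphabet_scheme()].
#' @param config A [diagram_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(scheme, config, path) {
  stopifnot(inherits(scheme, "alphabet_scheme"),
            inherits(config, "diagram_config"))
  doc <- list(
    groups = lapply(scheme$groups, paste, collapse = ""),
    gap_row_policy = scheme$gap_row_policy,
    filter = list(threshold = config$filter_threshold),
    geometry = list(
      column_spacing = config$column_spacing,
      row_spacing = config$row_spacing,
      group_gap = config$group_gap,
      max_ribbon_weight = config$max_ribbon_weight
    ),
    output = list(format = config$output_format),
    denominator = config$denominator_policy,
    gap_pairs = config$include_gap_pairs,
    dot_as_gap = config$dot_as_gap
  )
  if (length(scheme$ambiguity_symbols) > 0) {
    doc$ambiguity <- as.list(scheme$ambiguity_symbols)
  }
  if (length(scheme$aliases) > 0) {
    doc$aliases <- as.list(scheme$aliases)
  }
  if (!is.null(config$group_colors)) {
    doc$colors <- as.list(config$group_colors)
  }
  if (length(config$masked_positions) > 0) {
    doc$mask <- as.list(config$masked_positions)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
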