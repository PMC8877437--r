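# Mass-delta biotransformation rules and parent-mass dereplication.
#
# All arithmetic is on the m/z axis under a uniform [M+H]+ assumption: the
# proton cancels in substrate-product differences, so rule deltas apply to
# precursor m/z exactly as to neutral monoisotopic masses.

# Monoisotopic masses of the most abundant isotopes (Da).
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Mass of a proton (Da), for [M+H]+ adduct arithmetic
#' @export
PROTON_MASS <- 1.00727646688

#' Signed monoisotopic mass delta of a formula change
#'
#' Parses a textual gain/loss such as `"-CO2"`, `"+CH2"` or `"-C2H4"`
#' (ASCII or Unicode minus) and returns the signed sum of element
#' monoisotopic masses.
#'
#' @param formula_change Character scalar: sign followed by an element
#'   formula over C, H, N, O, P, S.
#' @return Signed mass delta in Da.
#' @export
formula_mass_delta <- function(formula_change) {
  s <- gsub("[−–]", "-", trimws(formula_change))
  sign <- 1
  if (startsWith(s, "-")) { sign <- -1; s <- substring(s, 2) }
  else if (startsWith(s, "+")) s <- substring(s, 2)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("cannot parse formula change: '", formula_change, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  total <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    cnt <- sub("^[A-Za-z]+", "", tk)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(.ELEMENT_MASS))
      stop("unknown element '", el, "' in '", formula_change, "'")
    total <- total + cnt * .ELEMENT_MASS[[el]]
  }
  sign * total
}

#' Construct a biotransformation rule
#'
#' A rule is a named, signed monoisotopic mass delta applied substrate to
#' product (negative = neutral loss). When `mass_delta` is omitted it is
#' computed from `formula_change` via element monoisotopic masses.
#'
#' @param rule_name Rule name, unique within a rule set.
#' @param formula_change Textual gain/loss, e.g. `"-CO2"`.
#' @param mass_delta Signed delta in Da; computed from the formula if `NULL`.
#' @param source `"builtin"` or `"user"`.
#' @return One-row data.frame with columns `rule_name`, `formula_change`,
#'   `mass_delta`, `source`.
#' @export
biotransform_rule <- function(rule_name, formula_change, mass_delta = NULL,
                              source = "user") {
  if (is.null(mass_delta)) mass_delta <- formula_mass_delta(formula_change)
  if (mass_delta == 0) stop("rule '", rule_name, "' has zero mass delta")
  data.frame(rule_name = rule_name, formula_change = formula_change,
             mass_delta = as.numeric(mass_delta), source = source,
             stringsAsFactors = FALSE)
}

.validate_rules <- function(rules) {
  need <- c("rule_name", "formula_change", "mass_delta", "source")
  if (!all(need %in% names(rules)))
    stop("rule set must have columns: ", paste(need, collapse = ", "))
  if (any(rules$mass_delta == 0)) stop("rule with zero mass delta")
  if (anyDuplicated(rules$rule_name))
    stop("duplicated rule name: ",
         rules$rule_name[duplicated(rules$rule_name)][1])
  rules
}

#' Built-in microbial biotransformation rules
#'
#' The common gut-microbial transformations of dietary phenolics, with mass
#' deltas computed from element monoisotopic masses (never from rounded
#' literature prints): decarboxylation (-CO2), dehydroxylation (-O),
#' catechol O-methylation (+CH2), carbon-carbon double bond reduction (+H2),
#' beta-oxidation shortening of a carboxylic acid side chain (-C2H4), and
#' glucuronidation (+C6H8O6).
#'
#' @return data.frame of rules (one per row) with `source = "builtin"`.
#' @export
builtin_rules <- function() {
  specs <- list(
    c("decarboxylation", "-CO2"),
    c("dehydroxylation", "-O"),
    c("catechol_O_methylation", "+CH2"),
    c("double_bond_reduction", "+H2"),
    c("beta_oxidation", "-C2H4"),
    c("glucuronidation", "+C6H8O6"))
  rules <- do.call(rbind, lapply(specs, function(s)
    biotransform_rule(s[1], s[2], source = "builtin")))
  .validate_rules(rules)
}

#' Read/write a biotransformation rule table (CSV)
#'
#' Columns: `rule_name`, `formula_change`, optional `mass_delta` (computed
#' from the formula when absent).
#'
#' @param path CSV path.
#' @param source Source tag assigned to read rules.
#' @return Rule data.frame (reader); `path` invisibly (writer).
#' @export
read_rules <- function(path, source = "user") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rule_name", "formula_change") %in% names(df)))
    stop("rule CSV needs columns rule_name, formula_change")
  if (is.null(df$mass_delta))
    df$mass_delta <- vapply(df$formula_change, formula_mass_delta, numeric(1))
  df$source <- source
  .validate_rules(df[c("rule_name", "formula_change", "mass_delta", "source")])
}

#' @rdname read_rules
#' @param rules Rule data.frame.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(rules, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Compound database

#' Construct / read a reference compound table
#'
#' `compound_db()` validates a table of reference compounds and attaches the
#' computed `[M+H]+` adduct m/z (`monoisotopic_mass + PROTON_MASS`);
#' `read_compound_db()` reads the CSV form (`compound_name`,
#' `monoisotopic_mass`, optional `smiles`).
#'
#' @param df data.frame with `compound_name` and `monoisotopic_mass`
#'   (optionally `smiles`).
#' @return data.frame with an added `adduct_mz` column.
#' @export
compound_db <- function(df) {
  if (!all(c("compound_name", "monoisotopic_mass") %in% names(df)))
    stop("compound table needs columns compound_name, monoisotopic_mass")
  if (any(df$monoisotopic_mass <= 0)) stop("nonpositive monoisotopic mass")
  df$adduct_mz <- df$monoisotopic_mass + PROTON_MASS
  if (is.null(df$smiles)) df$smiles <- NA_character_
  df[c("compound_name", "monoisotopic_mass", "adduct_mz", "smiles")]
}

#' @rdname compound_db
#' @param path CSV path.
#' @export
read_compound_db <- function(path) {
  compound_db(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# Rule application

#' Predict candidate product m/z for a substrate
#'
#' One candidate per rule: `product_mz = substrate_mz + mass_delta`;
#' candidates with nonpositive product m/z are dropped.
#'
#' @param substrate_mz Substrate precursor m/z in Da.
#' @param rules Rule data.frame (see [builtin_rules()]).
#' @return data.frame `rule_name`, `mass_delta`, `product_mz`.
#' @export
predict_product_mzs <- function(substrate_mz, rules) {
  out <- data.frame(rule_name = rules$rule_name,
                    mass_delta = rules$mass_delta,
                    product_mz = substrate_mz + rules$mass_delta,
                    stringsAsFactors = FALSE)
  out <- out[out$product_mz > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match an observed substrate/product mass difference against rules
#'
#' Returns every rule whose signed delta explains the observed difference:
#' `|(product_mz - substrate_mz) - mass_delta| <= tol`, sorted by absolute
#' mass error ascending.
#'
#' @param substrate_mz,product_mz Precursor m/z in Da.
#' @param rules Rule data.frame.
#' @param tol Mass tolerance in Da (> 0; default 0.02).
#' @return data.frame `rule_name`, `mass_delta`, `mass_error`.
#' @export
match_rule <- function(substrate_mz, product_mz, rules, tol = 0.02) {
  if (tol <= 0) stop("tol must be > 0")
  err <- (product_mz - substrate_mz) - rules$mass_delta
  keep <- which(abs(err) <= tol)
  out <- data.frame(rule_name = rules$rule_name[keep],
                    mass_delta = rules$mass_delta[keep],
                    mass_error = err[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$mass_error), out$rule_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Substrate dereplication

.derep_mz <- function(query_mz, db, parent_tol) {
  err <- query_mz - db$adduct_mz
  keep <- which(abs(err) <= parent_tol)
  out <- data.frame(compound_name = db$compound_name[keep],
                    adduct_mz = db$adduct_mz[keep],
                    mass_error = err[keep],
                    match_level = rep("parent_mass_only", length(keep)),
                    stringsAsFactors = FALSE)
  out[order(abs(out$mass_error), out$compound_name), , drop = FALSE]
}

#' Dereplicate a network node against a compound database
#'
#' Parent-mass matching of the node's consensus precursor against the
#' `[M+H]+` adduct m/z of each reference compound: every compound within
#' `parent_tol` yields an annotation, sorted by absolute mass error.
#' Fragmentation-level matching is not performed (for precursors below
#' 200 Da parent-mass matching is the only applicable level in any case),
#' so `match_level` is always `"parent_mass_only"`.
#'
#' @param node A `consensus_node` (or anything with a `precursor_mz` field).
#' @param db Compound table from [compound_db()].
#' @param parent_tol Parent mass tolerance in Da (> 0; default 0.002).
#' @return data.frame `node_id`, `compound_name`, `adduct_mz`, `mass_error`,
#'   `match_level`; zero rows when nothing matches or the database is empty.
#' @export
dereplicate_substrate <- function(node, db, parent_tol = 0.002) {
  if (parent_tol <= 0) stop("parent_tol must be > 0")
  ann <- .derep_mz(node$precursor_mz, db, parent_tol)
  if (nrow(ann) > 0)
    ann <- cbind(data.frame(node_id = node$node_id, stringsAsFactors = FALSE),
                 ann)
  else
    ann <- cbind(data.frame(node_id = character(0)), ann)
  rownames(ann) <- NULL
  ann
}
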