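#' Quadrature grid over the latent ability scale
#'
#' Builds the fixed grid used for every integral over ability: equally spaced
#' nodes with standard-normal weights renormalized to sum to one
#' (Bock--Aitkin quadrature). The default — 61 nodes on \[-5, 5\] — covers the
#' ability range over which a reading-comprehension form is informative with
#' margin on both sides.
#'
#' @param n_nodes Number of quadrature nodes (default 61).
#' @param bounds Length-2 numeric, the ability interval spanned.
#' @param weights Optional nonnegative weights, one per node; renormalized to
#'   sum to 1. Defaults to standard-normal density at the nodes.
#' @return A tibble with columns `node` (strictly increasing) and `weight`
#'   (nonnegative, summing to 1).
#' @examples
#' grid <- ability_grid()
#' sum(grid$weight) # 1
#' @export
ability_grid <- function(n_nodes = 61, bounds = c(-5, 5), weights = NULL) {
  check_finite(bounds, "bounds")
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing length-2 numeric.", class = "neatlink_invalid_argument")
  }
  if (n_nodes < 2) abort("`n_nodes` must be at least 2.", class = "neatlink_invalid_argument")
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- weights %||% dnorm(nodes)
  check_finite(w, "weights")
  if (length(w) != n_nodes || any(w < 0) || sum(w) <= 0) {
    abort("`weights` must be nonnegative, one per node.", class = "neatlink_invalid_argument")
  }
  tibble(node = nodes, weight = w / sum(w))
}

validate_grid <- function(grid) {
  if (!is.data.frame(grid) || !all(c("node", "weight") %in% names(grid))) {
    abort("`grid` must be a data frame with columns `node` and `weight`.",
          class = "neatlink_invalid_argument")
  }
  if (is.unsorted(grid$node, strictly = TRUE)) {
    abort("Grid nodes must be strictly increasing.", class = "neatlink_invalid_argument")
  }
  if (abs(sum(grid$weight) - 1) > 1e-10 || any(grid$weight < 0)) {
    abort("Grid weights must be nonnegative and sum to 1 (tolerance 1e-10).",
          class = "neatlink_invalid_argument")
  }
  invisible(grid)
}

#' Construct an item bank
#'
#' An item bank is a tibble with one row per item: identifiers, content
#' metadata (text, question type, anchor flag) and 2PL parameters. All
#' downstream operations (characteristic curves, linking, equating) take this
#' tibble.
#'
#' @param item_id Character, unique within the bank. Anchor items share
#'   `item_id` across the two forms' banks.
#' @param a Discrimination (logistic metric, no 1.7 scaling constant).
#' @param b Difficulty, on the ability scale.
#' @param form_id,text_id,question_type,is_anchor Content metadata. Question
#'   types follow the instrument's taxonomy: LIT (literal retention), TC
#'   (text-connecting inference), GAP (gap-filling inference), SM (situation
#'   model).
#' @param se_a,se_b Optional standard errors (`NA` when unavailable).
#' @param reliability Optional per-item reliability in \[0, 1\]; computed from
#'   `a` via [item_reliability()] when `NULL`.
#' @return A tibble with class-checked columns.
#' @examples
#' item_bank(item_id = c("i1", "i2"), a = c(1.2, 0.8), b = c(-0.5, 1))
#' @export
item_bank <- function(item_id, a, b, form_id = "F", text_id = "T1",
                      question_type = "TC", is_anchor = FALSE,
                      se_a = NA_real_, se_b = NA_real_, reliability = NULL) {
  bank <- tibble(
    item_id = as.character(item_id), form_id = form_id, text_id = text_id,
    question_type = question_type, is_anchor = is_anchor,
    a = as.numeric(a), b = as.numeric(b),
    se_a = as.numeric(se_a), se_b = as.numeric(se_b),
    reliability = if (is.null(reliability)) item_reliability(a) else as.numeric(reliability)
  )
  validate_item_bank(bank)
}

#' Validate an item bank tibble
#'
#' @param bank A data frame with at least `item_id`, `a`, `b`.
#' @param require_anchor Require a non-empty anchor subset (needed for linking).
#' @return The bank, invisibly coerced to a tibble, or an error.
#' @export
validate_item_bank <- function(bank, require_anchor = FALSE) {
  if (!is.data.frame(bank) || nrow(bank) == 0) {
    abort("`bank` must be a non-empty data frame of items.", class = "neatlink_invalid_argument")
  }
  needed <- c("item_id", "a", "b")
  missing_cols <- setdiff(needed, names(bank))
  if (length(missing_cols)) {
    abort(paste0("`bank` lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "neatlink_invalid_argument")
  }
  if (anyDuplicated(bank$item_id)) {
    abort("Duplicate `item_id` in bank.", class = "neatlink_invalid_argument")
  }
  check_finite(bank$a, "a"); check_finite(bank$b, "b")
  if (!is.null(bank$reliability) && any(!is.na(bank$reliability) &
      (bank$reliability < 0 | bank$reliability > 1))) {
    abort("`reliability` must lie in [0, 1].", class = "neatlink_invalid_argument")
  }
  if (require_anchor && (is.null(bank$is_anchor) || !any(bank$is_anchor))) {
    abort("Bank used for linking must contain anchor items.", class = "neatlink_invalid_argument")
  }
  as_tibble(bank)
}

#' Item characteristic curve of a 2PL item
#'
#' \eqn{P(\theta) = 1 / (1 + \exp(-a(\theta - b)))}, the probability of a
#' correct response. Pure logistic metric (no 1.7 normal-ogive constant),
#' matching maximum-likelihood logit calibration.
#'
#' @param a,b Discrimination and difficulty.
#' @param theta Ability value(s).
#' @return Probabilities in (0, 1), vectorized over `theta`.
#' @examples
#' icc(a = 1, b = 0, theta = 0) # 0.5
#' @export
icc <- function(a, b, theta) {
  check_finite(a, "a"); check_finite(b, "b"); check_finite(theta, "theta")
  plogis(a * (theta - b))
}

#' Fisher information of a 2PL item
#'
#' \eqn{I(\theta) = a^2 P(\theta)(1 - P(\theta))}; maximal at \eqn{\theta = b}
#' with value \eqn{a^2/4}.
#'
#' @inheritParams icc
#' @return Nonnegative information values.
#' @export
item_information <- function(a, b, theta) {
  p <- icc(a, b, theta)
  a^2 * p * (1 - p)
}

#' Test characteristic curve (expected raw score)
#'
#' Sum of item characteristic curves over the bank; strictly increasing in
#' ability when all discriminations are positive, with range (0, number of
#' items).
#'
#' @param bank An item bank tibble.
#' @param theta Ability value(s).
#' @return Expected raw score at each `theta`.
#' @export
test_characteristic_curve <- function(bank, theta) {
  bank <- validate_item_bank(bank)
  check_finite(theta, "theta")
  vapply(theta, function(t) sum(plogis(bank$a * (t - bank$b))), numeric(1))
}

#' Test information function on a grid
#'
#' Pointwise sum of item informations over the bank, evaluated at the grid
#' nodes (the curve behind a test-information figure).
#'
#' @param bank An item bank tibble.
#' @param grid An [ability_grid()] tibble.
#' @return A tibble with columns `theta` and `information`.
#' @export
test_information <- function(bank, grid = ability_grid()) {
  bank <- validate_item_bank(bank)
  validate_grid(grid)
  info <- vapply(grid$node, function(t) sum(item_information(bank$a, bank$b, t)), numeric(1))
  tibble(theta = grid$node, information = info)
}

#' Per-item reliability from discrimination
#'
#' The proportion of latent response variance explained by ability under a
#' logistic link with standard-normal ability:
#' \eqn{R^2 = a^2 / (a^2 + \pi^2/3)}. An item with no discrimination explains
#' nothing (0); reliability approaches 1 as `a` grows.
#'
#' @param a Discrimination value(s).
#' @return Values in \[0, 1\].
#' @examples
#' item_reliability(1.814) # about 0.5
#' @export
item_reliability <- function(a) {
  check_finite(a, "a")
  a^2 / (a^2 + pi^2 / 3)
}

#' Read / write item banks
#'
#' CSV columns: item_id, form_id, text_id, question_type, is_anchor, a, b,
#' se_a, se_b, reliability (missing standard errors serialized as empty
#' fields). The JSON mirror holds the same records.
#'
#' @param path File path (`.csv` or `.json`).
#' @param bank An item bank tibble.
#' @return `read_item_bank()` returns a validated bank tibble;
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  bank <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(bank$is_anchor)) bank$is_anchor <- as.logical(bank$is_anchor)
  validate_item_bank(bank)
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  bank <- validate_item_bank(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(bank, path, dataframe = "rows", na = "null", digits = NA)
  } else {
    readr::write_csv(bank, path, na = "")
  }
  invisible(path)
}
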