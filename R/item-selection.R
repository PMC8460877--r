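#' Anchor-ratio cap on form length
#'
#' Under the rule of thumb that the common-item set should be at least a
#' given fraction of the full test, `n_anchor` anchors allow a form of at
#' most `floor(n_anchor / ratio)` items, of which
#' `floor(n_anchor / ratio) - n_anchor` are form-specific. Nine anchors at
#' 20% allow 45 items, 36 of them unique.
#'
#' @param n_anchor Number of anchor items (>= 1).
#' @param ratio Minimum anchor share of the full form (default 0.20).
#' @return A tibble `max_total`, `max_unique`.
#' @examples
#' anchor_ratio_cap(9, 0.20) # 45 total, 36 unique
#' @export
anchor_ratio_cap <- function(n_anchor, ratio = 0.20) {
  if (n_anchor < 1) abort("`n_anchor` must be >= 1.", class = "neatlink_invalid_argument")
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1) {
    abort("`ratio` must lie in (0, 1].", class = "neatlink_invalid_argument")
  }
  max_total <- floor(n_anchor / ratio)
  tibble(max_total = max_total, max_unique = max_total - n_anchor)
}

#' Selection plan
#'
#' Per-text, per-question-type quotas applied identically to both members of
#' each text pair, under the anchor-ratio cap. The packaged default
#' ([default_selection_plan()]) is the reduced forms' layout: 33 unique items
#' per form over 7 texts, with 9 anchors at a 20% ratio.
#'
#' @param quotas Tibble `text_id`, `question_type`, `n` (identical for both
#'   forms of a text pair).
#' @param n_anchor Number of anchors.
#' @param anchor_ratio Minimum anchor share (default 0.20).
#' @return A `neatlink_plan` list with `quotas`, `n_anchor`, `anchor_ratio`,
#'   `max_unique_per_form`.
#' @export
selection_plan <- function(quotas, n_anchor = 9, anchor_ratio = 0.20) {
  cap <- anchor_ratio_cap(n_anchor, anchor_ratio)
  if (sum(quotas$n) > cap$max_unique) {
    abort(sprintf("Quotas request %d unique items but the anchor ratio allows %d.",
                  sum(quotas$n), cap$max_unique), class = "neatlink_invalid_argument")
  }
  structure(list(quotas = as_tibble(quotas), n_anchor = n_anchor,
                 anchor_ratio = anchor_ratio,
                 max_unique_per_form = cap$max_unique),
            class = "neatlink_plan")
}

#' @rdname selection_plan
#' @export
default_selection_plan <- function() {
  selection_plan(reduced_form_layout("A"), n_anchor = 9, anchor_ratio = 0.20)
}

# difficulty stratum used by the heterogeneity tie-break
b_stratum <- function(b) cut(b, c(-Inf, -1, 1, Inf), labels = c("low", "mid", "high"))

# greedy pick of `quota` items from one (text, type) cell: highest a first;
# candidates within 0.05 of the best compete, and the one whose difficulty
# falls in the stratum least covered so far in this text wins; remaining ties
# by item_id order
greedy_pick <- function(cell, quota, stratum_counts, a_window = 0.05) {
  picked <- character(0)
  pool <- cell
  for (k in seq_len(quota)) {
    a_max <- max(pool$a)
    near <- pool[pool$a >= a_max - a_window, , drop = FALSE]
    if (nrow(near) > 1) {
      cov <- stratum_counts[as.character(b_stratum(near$b))]
      near <- near[order(cov, near$item_id), , drop = FALSE]
    } else {
      near <- near[order(near$item_id), , drop = FALSE]
    }
    choice <- near$item_id[1]
    st <- as.character(b_stratum(near$b[1]))
    stratum_counts[st] <- stratum_counts[st] + 1
    picked <- c(picked, choice)
    pool <- pool[pool$item_id != choice, , drop = FALSE]
  }
  list(picked = picked, stratum_counts = stratum_counts)
}

select_form <- function(bank, plan, form_label) {
  quotas <- plan$quotas
  selected <- character(0)
  infeasible <- list()
  for (tx in unique(quotas$text_id)) {
    counts <- c(low = 0, mid = 0, high = 0) # difficulty coverage within text
    q_tx <- quotas[quotas$text_id == tx, ]
    for (r in seq_len(nrow(q_tx))) {
      qt <- q_tx$question_type[r]; quota <- q_tx$n[r]
      if (quota == 0) next
      cell <- bank |>
        filter(.data$text_id == tx, .data$question_type == qt, !.data$is_anchor) |>
        arrange(.data$item_id)
      if (nrow(cell) < quota) {
        infeasible <- c(infeasible, list(tibble(form = form_label, text_id = tx,
                                                question_type = qt,
                                                available = nrow(cell), quota = quota)))
        next
      }
      res <- greedy_pick(cell, quota, counts)
      selected <- c(selected, res$picked)
      counts <- res$stratum_counts
    }
  }
  list(selected = selected, infeasible = infeasible)
}

#' Select items under content pairing and the anchor-ratio rule
#'
#' Reduces the two forms' item pools: within each (text, question-type) cell
#' the plan's quota is filled greedily by discrimination, with near-ties
#' (within 0.05 on `a`) resolved toward the difficulty stratum — low
#' \eqn{(-\infty,-1]}, mid \eqn{(-1,1]}, high \eqn{(1,\infty)} — least
#' covered so far within the text, so the kept set is both discriminating
#' and heterogeneous in difficulty. Anchor items are always retained.
#' Selection is deterministic: identical inputs give identical selections.
#'
#' @param bank_from,bank_to Calibrated full banks of the two forms (anchors
#'   flagged with `is_anchor`).
#' @param plan A [selection_plan()] (default [default_selection_plan()]).
#' @return A `neatlink_selection` list: `bank_from`, `bank_to` (reduced banks
#'   including anchors), `achieved` (per-form, per-text, per-type counts),
#'   `summary` (kept/dropped discrimination and difficulty summaries per
#'   form), `dropped` (tibble of dropped items with reason).
#' @export
select_items <- function(bank_from, bank_to, plan = default_selection_plan()) {
  bank_from <- validate_item_bank(bank_from, require_anchor = TRUE)
  bank_to <- validate_item_bank(bank_to, require_anchor = TRUE)
  res_f <- select_form(bank_from, plan, "from")
  res_t <- select_form(bank_to, plan, "to")
  infeasible <- bind_rows(c(res_f$infeasible, res_t$infeasible))
  if (nrow(infeasible) > 0) {
    abort(paste0("Infeasible selection quota:\n",
                 paste(sprintf("- form %s, text %s, type %s: quota %d, available %d",
                               infeasible$form, infeasible$text_id,
                               infeasible$question_type, infeasible$quota,
                               infeasible$available), collapse = "\n")),
          class = "neatlink_infeasible_plan")
  }
  reduce <- function(bank, sel) {
    bank |> filter(.data$is_anchor | .data$item_id %in% sel)
  }
  out_from <- reduce(bank_from, res_f$selected)
  out_to <- reduce(bank_to, res_t$selected)
  achieved <- bind_rows(
    out_from |> filter(!.data$is_anchor) |> mutate(form = "from"),
    out_to |> filter(!.data$is_anchor) |> mutate(form = "to")) |>
    dplyr::count(.data$form, .data$text_id, .data$question_type, name = "n")
  summarise_side <- function(full, kept, label) {
    dropped <- full |> filter(!.data$item_id %in% kept$item_id)
    tibble(form = label,
           n_kept = nrow(kept), n_dropped = nrow(dropped),
           mean_a_kept = mean(kept$a), mean_a_pool = mean(full$a),
           sd_b_kept = sd(kept$b), sd_b_pool = sd(full$b))
  }
  dropped <- bind_rows(
    bank_from |> filter(!.data$item_id %in% out_from$item_id) |> mutate(form = "from"),
    bank_to |> filter(!.data$item_id %in% out_to$item_id) |> mutate(form = "to")) |>
    mutate(reason = "below_quota_rank")
  structure(list(
    bank_from = out_from, bank_to = out_to, achieved = achieved,
    summary = bind_rows(summarise_side(bank_from, out_from, "from"),
                        summarise_side(bank_to, out_to, "to")),
    dropped = dropped, plan = plan), class = "neatlink_selection")
}

#' @export
print.neatlink_selection <- function(x, ...) {
  cat("Item selection under the anchor-ratio rule\n")
  cat(sprintf("  from-form: %d kept (%d anchors); to-form: %d kept (%d anchors)\n",
              nrow(x$bank_from), sum(x$bank_from$is_anchor),
              nrow(x$bank_to), sum(x$bank_to$is_anchor)))
  invisible(x)
}

#' Read / write selection plans as JSON
#'
#' @param plan A `neatlink_plan`.
#' @param path JSON path.
#' @return `read_selection_plan()` returns the plan; the writer returns
#'   `path` invisibly.
#' @export
write_selection_plan <- function(plan, path) {
  jsonlite::write_json(list(quotas = plan$quotas, n_anchor = plan$n_anchor,
                            anchor_ratio = plan$anchor_ratio),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_plan
#' @export
read_selection_plan <- function(path) {
  raw <- jsonlite::fromJSON(path)
  selection_plan(as_tibble(raw$quotas), n_anchor = raw$n_anchor,
                 anchor_ratio = raw$anchor_ratio)
}
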