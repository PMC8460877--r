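# Shared fixtures, built in code. Heavy calibrations are memoised so several
# test files can reuse the same fitted objects within one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small hand-specified anchor bank used by linking tests
toy_anchors <- function() {
  item_bank(item_id = paste0("an", 1:9),
            a = c(1.0, 1.3, 0.7, 1.6, 0.9, 1.2, 1.45, 0.85, 1.1),
            b = c(-1.4, -0.9, -0.5, -0.2, 0.0, 0.3, 0.7, 1.0, 1.3),
            form_id = "ANCHOR", is_anchor = TRUE)
}

# simulated parallel 42-item forms at n = 2000 per group, both calibrated;
# used by round-trip, method-agreement and score-equating tests
parallel_fits <- function() {
  memo("parallel_fits", {
    study <- generate_neat_study(study_config(n_from = 2000, n_to = 2000, seed = 424))
    meta_f <- study$bank_from[c("item_id", "text_id", "question_type", "is_anchor")]
    meta_t <- study$bank_to[c("item_id", "text_id", "question_type", "is_anchor")]
    list(study = study,
         from = fit_2pl(study$responses_from, form_id = "A", item_meta = meta_f),
         to = fit_2pl(study$responses_to, form_id = "B", item_meta = meta_t))
  })
}

# one study-scale (427/321) simulated NEAT data set with its calibrations
study_fits <- function() {
  memo("study_fits", {
    study <- generate_neat_study(study_config(seed = 99))
    list(study = study,
         from = fit_2pl(study$responses_from, form_id = "A",
                        item_meta = study$bank_from[c("item_id", "text_id",
                                                      "question_type", "is_anchor")]),
         to = fit_2pl(study$responses_to, form_id = "B",
                      item_meta = study$bank_to[c("item_id", "text_id",
                                                  "question_type", "is_anchor")]))
  })
}

# brute-force distribution of a sum of independent Bernoulli variables by
# exhaustive enumeration over all 2^n response patterns (oracle for the
# Lord-Wingersky recursion)
enumerate_score_dist <- function(p) {
  n <- length(p)
  patterns <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(patterns, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  scores <- rowSums(patterns)
  vapply(0:n, function(s) sum(probs[scores == s]), numeric(1))
}
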