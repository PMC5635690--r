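# Shared helpers for the suite.

# Reference molecule label ("1Tc", "Ent dimer") -> enumerated candidate id
lab2id <- function(m) ifelse(grepl("^[0-9]", m), paste0("M", m), m)

# Default candidate set, enumerated once per test run
default_candidates <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(enumerate_candidates())
    cache
  }
})

candidate_by_id <- function(id, cands = default_candidates()) {
  ids <- vapply(cands, `[[`, "", "id")
  cands[[match(id, ids)]]
}

# Independent elemental-mass oracle used to freeze expected values: a plain
# lookup-and-sum kept deliberately separate from the package's formula
# arithmetic.
oracle_mass <- function(text) {
  em <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  sum(vapply(toks, function(t) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Z][a-z]?", "", t)
    em[[el]] * if (nzchar(n)) as.numeric(n) else 1
  }, 0))
}
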