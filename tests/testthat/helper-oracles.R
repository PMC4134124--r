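# Independent oracles and tiny fixture builders used across the suite.

# Naive O(n^2) gate check: enumerate every window anchored at each claim
# date and every discharge, independently of the rolling implementation.
brute_gate <- function(encounters, rule = gate_rule()) {
  qdates <- as.Date(character(0))
  disc <- sort(encounters$date[encounters$source == "discharge"])
  if (length(disc) >= rule$min_hospitalizations) {
    qdates <- c(qdates, disc[rule$min_hospitalizations])
  }
  claims <- sort(encounters$date[encounters$source == "claim"])
  for (t in as.numeric(claims)) {
    inside <- claims[as.numeric(claims) >= t &
                       as.numeric(claims) < t + rule$window_days]
    if (length(inside) >= rule$min_claims) {
      qdates <- c(qdates, sort(inside)[rule$min_claims])
    }
  }
  if (length(qdates) == 0) {
    list(qualifies = FALSE, qualifying_date = as.Date(NA))
  } else {
    list(qualifies = TRUE, qualifying_date = min(qdates))
  }
}

# Random small encounter set for one person (IBD-mapped codes only).
random_encounters <- function(n_claims, n_discharges, span_days = 2000,
                              origin = as.Date("1996-01-01")) {
  n <- n_claims + n_discharges
  enc <- tibble::tibble(
    person_id = "X",
    date = origin + sample.int(span_days, n, replace = TRUE),
    source = c(rep("claim", n_claims), rep("discharge", n_discharges)),
    icd_version = 9L,
    code = sample(c("555.9", "556.9"), n, replace = TRUE)
  )
  enc[order(enc$date), ]
}

# Minimal one-person registry for ascertainment tests.
one_person_registry <- function(id = "X", sex = "female",
                                birth = as.Date("1970-06-15")) {
  tibble::tibble(person_id = id, sex = sex, birth_date = birth,
                 cover_start = as.Date("1991-01-01"),
                 cover_end = as.Date("2010-12-31"))
}

# Encounter rows from a compact spec: dates, sources, diseases.
make_encounters <- function(id, dates, sources, diseases,
                            icd_version = 9L) {
  codes <- ifelse(diseases == "CD",
                  ifelse(icd_version == 9L, "555.9", "K50.9"),
                  ifelse(icd_version == 9L, "556.9", "K51.9"))
  tibble::tibble(person_id = id, date = as.Date(dates), source = sources,
                 icd_version = icd_version, code = codes)
}
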