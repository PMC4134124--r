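#' Map an ICD diagnosis code to an IBD phenotype
#'
#' Classifies diagnosis codes into Crohn's disease (CD), ulcerative colitis
#' (UC) or `none`. Matching is prefix-based on the code stem before the
#' decimal point: ICD-9 stems `555` -> CD, `556` -> UC; ICD-10 stems `K50` ->
#' CD, `K51` -> UC (case-insensitive). Codes recorded without the decimal
#' (`"5559"`, `"K509"`) match the same stems. Anything else maps to `none`;
#' unknown codes are never an error.
#'
#' @param code character vector of ICD codes (non-empty strings).
#' @param icd_version integer vector (9 or 10), recycled if length 1.
#' @return character vector in `{"CD", "UC", "none"}`.
#' @examples
#' map_code(c("556.1", "K50.0", "250.0"), c(9, 10, 9))
#' @export
map_code <- function(code, icd_version) {
  code <- as.character(code)
  if (length(code) == 0) return(character(0))
  if (anyNA(code) || any(!nzchar(trimws(code)))) {
    stop("`code` must be non-empty")
  }
  icd_version <- as.integer(icd_version)
  if (length(icd_version) == 1) icd_version <- rep(icd_version, length(code))
  if (length(icd_version) != length(code)) {
    stop("`icd_version` must have length 1 or length(code)")
  }
  stem <- toupper(sub("\\..*$", "", trimws(code)))
  out <- rep("none", length(code))
  i9 <- icd_version == 9L
  out[i9 & startsWith(stem, "555")] <- "CD"
  out[i9 & startsWith(stem, "556")] <- "UC"
  i10 <- icd_version == 10L
  out[i10 & startsWith(stem, "K50")] <- "CD"
  out[i10 & startsWith(stem, "K51")] <- "UC"
  out
}

#' Case-definition gate and scoring parameters
#'
#' `gate_rule()` holds the IBD entry criterion: at least
#' `min_hospitalizations` hospital discharges, or `min_claims` physician
#' claims within a rolling window of `window_days` days, all carrying IBD
#' diagnosis codes. `score_weights()` holds the phenotype scoring weights
#' (each UC-coded claim +1, CD-coded claim -1, UC-coded discharge +2,
#' CD-coded discharge -2) and the classification thresholds: cumulative score
#' strictly greater than `uc_threshold` is UC, strictly less than
#' `cd_threshold` is CD, anything between (inclusive) is undifferentiated IBD
#' (IBDU).
#'
#' @param min_hospitalizations,min_claims positive integer counts.
#' @param window_days length of the rolling claim window in days (half-open,
#'   `[t, t + window_days)`).
#' @return a classed list of validated parameters.
#' @export
gate_rule <- function(min_hospitalizations = 1L, min_claims = 4L,
                      window_days = 730L) {
  r <- list(min_hospitalizations = as.integer(min_hospitalizations),
            min_claims = as.integer(min_claims),
            window_days = as.integer(window_days))
  for (f in names(r)) {
    if (is.na(r[[f]]) || r[[f]] < 1) stop_config(f, "must be a positive integer")
  }
  structure(r, class = "gate_rule")
}

#' @rdname gate_rule
#' @param claim_uc,claim_cd,discharge_uc,discharge_cd per-encounter scores.
#' @param uc_threshold,cd_threshold classification cut points.
#' @export
score_weights <- function(claim_uc = 1L, claim_cd = -1L,
                          discharge_uc = 2L, discharge_cd = -2L,
                          uc_threshold = 2L, cd_threshold = -2L) {
  w <- list(claim_uc = as.integer(claim_uc), claim_cd = as.integer(claim_cd),
            discharge_uc = as.integer(discharge_uc),
            discharge_cd = as.integer(discharge_cd),
            uc_threshold = as.integer(uc_threshold),
            cd_threshold = as.integer(cd_threshold))
  if (w$cd_threshold >= w$uc_threshold) {
    stop_config("cd_threshold", "must be less than uc_threshold")
  }
  if (w$claim_uc <= 0 || w$discharge_uc <= 0) {
    stop_config("claim_uc/discharge_uc", "UC weights must be positive")
  }
  if (w$claim_cd >= 0 || w$discharge_cd >= 0) {
    stop_config("claim_cd/discharge_cd", "CD weights must be negative")
  }
  structure(w, class = "score_weights")
}

#' Test the IBD case-definition gate for one person
#'
#' A person enters the IBD cohort if they have at least one hospital
#' discharge, or at least `rule$min_claims` physician claims within any
#' half-open window `[t, t + window_days)`, all with IBD diagnosis codes.
#' Windows are anchored at each claim date (anchoring at claims loses no
#' window: sliding a window left until it touches a claim changes no count).
#'
#' @param encounters encounters of a single person, already restricted to
#'   IBD-mapped codes and **sorted by date**; a data frame with columns
#'   `date` (Date) and `source` (`"claim"` or `"discharge"`).
#' @param rule a [gate_rule()].
#' @return list with `qualifies` (logical) and `qualifying_date` (the earliest
#'   date at which the criterion is first met: the date of the
#'   `min_hospitalizations`-th discharge or of the `min_claims`-th claim in
#'   the earliest qualifying window, whichever is earlier; `NA` if the gate
#'   fails).
#' @export
meets_ibd_gate <- function(encounters, rule = gate_rule()) {
  if (nrow(encounters) == 0) {
    return(list(qualifies = FALSE, qualifying_date = as.Date(NA)))
  }
  if (is.unsorted(encounters$date)) {
    stop("contract violation: encounters must be sorted by date")
  }
  qdates <- as.Date(character(0))

  disc <- encounters$date[encounters$source == "discharge"]
  if (length(disc) >= rule$min_hospitalizations) {
    qdates <- c(qdates, disc[rule$min_hospitalizations])
  }

  claims <- encounters$date[encounters$source == "claim"]
  n <- length(claims)
  if (n >= rule$min_claims) {
    d <- as.numeric(claims)
    # claims in [d[i], d[i] + window): count via position of last date < bound
    upper <- findInterval(d + rule$window_days - 0.5, d)
    hit <- which(upper - seq_len(n) + 1 >= rule$min_claims)
    if (length(hit) > 0) {
      qdates <- c(qdates, min(claims[hit + rule$min_claims - 1]))
    }
  }

  if (length(qdates) == 0) {
    list(qualifies = FALSE, qualifying_date = as.Date(NA))
  } else {
    list(qualifies = TRUE, qualifying_date = min(qdates))
  }
}

#' Cumulative phenotype score for one person
#'
#' Sums per-encounter weights over IBD-mapped encounters: UC-coded claims
#' count `+1`, CD-coded claims `-1`, UC-coded discharges `+2`, CD-coded
#' discharges `-2` (configurable via [score_weights()]). A patient with one
#' UC-coded discharge and one UC-coded claim therefore scores `+3`.
#'
#' @param encounters data frame of one person's IBD-mapped encounters with
#'   columns `source` and either a `disease` column (`"CD"`/`"UC"`) or
#'   `code` + `icd_version` from which it is derived.
#' @param weights a [score_weights()].
#' @return integer score (0 for an empty encounter set).
#' @export
cumulative_score <- function(encounters, weights = score_weights()) {
  if (nrow(encounters) == 0) return(0L)
  disease <- if ("disease" %in% names(encounters)) {
    encounters$disease
  } else {
    map_code(encounters$code, encounters$icd_version)
  }
  if (any(!disease %in% c("CD", "UC"))) {
    stop("contract violation: encounters must be restricted to IBD-mapped codes")
  }
  is_claim <- encounters$source == "claim"
  w <- ifelse(disease == "UC",
              ifelse(is_claim, weights$claim_uc, weights$discharge_uc),
              ifelse(is_claim, weights$claim_cd, weights$discharge_cd))
  as.integer(sum(w))
}

#' Classify a cumulative score into CD / UC / IBDU
#'
#' UC if the score is strictly greater than `weights$uc_threshold` (+2 by
#' default), CD if strictly less than `weights$cd_threshold` (-2), otherwise
#' undifferentiated IBD. The three labels partition the integers.
#'
#' @param score integer vector of cumulative scores.
#' @param weights a [score_weights()].
#' @return character vector in `{"CD", "UC", "IBDU"}`.
#' @export
classify_score <- function(score, weights = score_weights()) {
  ifelse(score > weights$uc_threshold, "UC",
         ifelse(score < weights$cd_threshold, "CD", "IBDU"))
}

#' Washout (run-in) exclusion for one person
#'
#' A person is excluded as prevalent if any IBD-mapped encounter falls in a
#' calendar year inside the washout span (inclusive on both ends). The
#' default study design uses 1991-1995 as washout before a 1996-2009 study
#' span.
#'
#' @param encounters one person's IBD-mapped encounters (`date` column).
#' @param washout_span integer `c(first_year, last_year)`.
#' @return `TRUE` if the person is excluded (prevalent), else `FALSE`.
#' @export
apply_washout <- function(encounters, washout_span = c(1991L, 1995L)) {
  if (nrow(encounters) == 0) return(FALSE)
  yr <- year_of(encounters$date)
  any(yr >= washout_span[1] & yr <= washout_span[2])
}

#' Ascertain incident IBD cases from registry and encounter streams
#'
#' Runs the full case definition over every person: map diagnosis codes and
#' keep IBD-coded encounters; exclude persons with any IBD-coded encounter in
#' the washout span (prevalent cases); apply the hospitalizations-or-claims
#' gate; date the diagnosis at the first IBD-coded contact on/after the study
#' start; score encounters in the classification window and label the case
#' CD, UC or IBDU. Persons whose diagnosis year falls outside `study_span`
#' are dropped.
#'
#' @param registry person table (`person_id`, `sex`, `birth_date`,
#'   `cover_start`, `cover_end`); `person_id` must be unique.
#' @param encounters encounter table (`person_id`, `date`, `source`,
#'   `icd_version`, `code`); every `person_id` must appear in the registry.
#' @param gate a [gate_rule()].
#' @param weights a [score_weights()].
#' @param washout_span,study_span integer year pairs. In the default design
#'   the washout (1991-1995) immediately precedes the study span (1996-2009).
#' @param classification_window_days encounters from the diagnosis date
#'   through this many days later feed the cumulative score (default 730,
#'   mirroring the two-year gate horizon); `NULL` scores all follow-up.
#' @return tibble of case records: `person_id`, `diagnosis_date`,
#'   `diagnosis_year`, `score`, `category`, `n_claims`, `n_discharges`.
#' @export
ascertain_cases <- function(registry, encounters,
                            gate = gate_rule(), weights = score_weights(),
                            washout_span = c(1991L, 1995L),
                            study_span = c(1996L, 2009L),
                            classification_window_days = 730) {
  check_columns(registry, c("person_id", "sex", "birth_date"), "registry")
  check_columns(encounters, c("person_id", "date", "source", "icd_version",
                              "code"), "encounters")
  if (anyDuplicated(registry$person_id)) {
    stop("data error: duplicate person_id in registry")
  }
  empty <- tibble(person_id = character(0),
                  diagnosis_date = as.Date(character(0)),
                  diagnosis_year = integer(0), score = integer(0),
                  category = character(0), n_claims = integer(0),
                  n_discharges = integer(0))
  if (nrow(encounters) == 0) return(empty)
  if (!all(encounters$person_id %in% registry$person_id)) {
    stop("data error: encounters reference persons missing from the registry")
  }

  enc <- as_tibble(encounters)
  enc$disease <- map_code(enc$code, enc$icd_version)
  enc <- enc[enc$disease != "none", , drop = FALSE]
  if (nrow(enc) == 0) return(empty)
  enc <- enc[order(enc$person_id, enc$date), , drop = FALSE]

  study_start <- jan1(study_span[1])
  rows <- lapply(split(enc, enc$person_id, drop = TRUE), function(e) {
    if (apply_washout(e, washout_span)) return(NULL)
    g <- meets_ibd_gate(e, gate)
    if (!g$qualifies) return(NULL)
    on_study <- e$date[e$date >= study_start]
    if (length(on_study) == 0) return(NULL)
    dx_date <- on_study[1]
    dx_year <- year_of(dx_date)
    if (dx_year < study_span[1] || dx_year > study_span[2]) return(NULL)
    win <- if (is.null(classification_window_days)) {
      e[e$date >= dx_date, , drop = FALSE]
    } else {
      e[e$date >= dx_date &
          e$date <= dx_date + classification_window_days, , drop = FALSE]
    }
    s <- cumulative_score(win, weights)
    tibble(person_id = e$person_id[1], diagnosis_date = dx_date,
           diagnosis_year = dx_year, score = s,
           category = classify_score(s, weights),
           n_claims = sum(win$source == "claim"),
           n_discharges = sum(win$source == "discharge"))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}
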