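# Controlled symptom vocabulary. Severity is a property of the symptom
# token, except "feeling hot", which escalates to severe (fever) only when
# a recorded body temperature exceeds 38.9 degrees C.

#' Symptom vocabularies
#'
#' Controlled vocabularies used by the questionnaire classifier. Mild and
#' severe lists follow the symptom checklist used in BNT162b2 reactogenicity
#' monitoring; "feeling hot" is mild unless accompanied by a recorded
#' temperature above 38.9 C, in which case it counts as fever (severe).
#'
#' @format Character vectors of lower-case symptom tokens.
#' @export
mild_symptoms <- c(
  "abdominal pain", "feeling hot", "back or neck pain", "feeling cold",
  "muscle pain", "weakness", "headache", "dizziness", "vomiting",
  "sore throat", "diarrhea", "cough", "leg pain", "ear pain",
  "loss of taste and smell", "swelling of the lymph nodes",
  "fast heartbeat", "hypertension"
)

#' @rdname mild_symptoms
#' @export
severe_symptoms <- c("chest pain", "dyspnea", "fever", "confusion", "chills")

#' @rdname mild_symptoms
#' @export
all_symptoms <- c(mild_symptoms, severe_symptoms)

# temperature strictly above this is fever (severe); at or below, mild
.FEVER_THRESHOLD_C <- 38.9

# tier codes, ordered
.TIERS <- c("none", "mild", "severe")

tier_rank <- function(tier) match(tier, .TIERS)

# split a semicolon-joined symptom field into a character vector
split_symptoms <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  s <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  tolower(s[nzchar(s)])
}

join_symptoms <- function(x) paste(x, collapse = ";")
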