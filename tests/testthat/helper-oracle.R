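# Independent brute-force scorer used to cross-check the engine. Kept
# deliberately naive: every argument is tested for activation on its own and
# contributions are summed with explicit branches; no engine code paths are
# reused for atom evaluation or aggregation.

oracle_atom_holds <- function(atom, facts) {
  v <- facts[[atom$field]]
  if (is.null(v) || (length(v) == 1 && is.na(v))) return(FALSE)
  if (atom$kind == "comparison") {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) return(FALSE)
    if (atom$operator == ">") return(x > atom$operand)
    if (atom$operator == "<") return(x < atom$operand)
    return(x == atom$operand)
  }
  if (atom$kind == "range") {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) return(FALSE)
    return(x >= atom$operand[1] && x <= atom$operand[2])
  }
  s <- tolower(as.character(v))
  if (identical(atom$operand, "true")) return(s %in% c("true", "yes", "1"))
  s == atom$operand
}

oracle_plan_scores <- function(patient, evidence, mode = "literal", tau = 0) {
  plans <- unique(vapply(evidence, `[[`, character(1), "plan"))
  clin <- stats::setNames(numeric(length(plans)), plans)
  val <- clin
  for (a in evidence) {
    if (tolower(a$disease) != tolower(patient$disease)) next
    active <- TRUE
    for (atom in a$condition$atoms) {
      if (!oracle_atom_holds(atom, patient$facts)) { active <- FALSE; break }
    }
    if (!active) next
    if (a$evidence_kind == "clinical") {
      if (a$support_type == "positive") {
        clin[a$plan] <- clin[a$plan] + a$weight
      } else {
        clin[a$plan] <- clin[a$plan] - a$weight
      }
    } else {
      held <- a$required_values %in% names(patient$values)
      if (!all(held)) next
      w <- unname(patient$values[a$required_values])
      if (any(w <= tau)) next
      v <- min(w)
      if (a$support_type == "negative") {
        val[a$plan] <- val[a$plan] - a$weight * v
      } else if (mode == "literal") {
        val[a$plan] <- val[a$plan] + a$weight
      } else {
        val[a$plan] <- val[a$plan] + a$weight * v
      }
    }
  }
  list(clinical = clin, value = val)
}
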