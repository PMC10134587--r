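# Small in-code fixtures shared across test files.

# 3-diagnosis knowledge base: two actual diagnoses (4 defining
# characteristics + 1 related factor each) and one risk diagnosis
# (3 risk factors), five items (one per aspect).
tiny_kb <- function() {
  items <- data.frame(
    item_id = sprintf("I-%03d", 1:5),
    aspect = KB_ASPECTS,
    label = paste("tiny item", 1:5),
    stringsAsFactors = FALSE)
  actual_dx <- function(code) {
    list(dx_code = code, label = paste("tiny actual", code),
         dx_type = "actual",
         elements = data.frame(
           element_id = c(sprintf("%s-DC%02d", code, 1:4),
                          sprintf("%s-RF01", code)),
           element_type = c(rep("defining_characteristic", 4),
                            "related_factor"),
           label = paste(code, "element", 1:5),
           stringsAsFactors = FALSE))
  }
  risk_dx <- list(
    dx_code = "DX-003", label = "tiny risk DX-003", dx_type = "risk",
    elements = data.frame(
      element_id = sprintf("DX-003-RK%02d", 1:3),
      element_type = "risk_factor",
      label = paste("DX-003 risk factor", 1:3),
      stringsAsFactors = FALSE))
  diagnoses <- list(actual_dx("DX-001"), actual_dx("DX-002"), risk_dx)
  associations <- do.call(rbind, lapply(diagnoses, function(d) {
    data.frame(item_id = rep_len(items$item_id, nrow(d$elements)),
               dx_code = d$dx_code,
               element_id = d$elements$element_id,
               stringsAsFactors = FALSE)
  }))
  knowledge_base(diagnoses, items, associations = associations,
                 meta = list(engine = "fixture"))
}

# one care-plan row as the reader would produce it
plan_row <- function(participant = "S-01", patient = "P-01",
                     group = "control", phase = "pretest",
                     role = "student", dx = "DX-001",
                     elements = character()) {
  out <- data.frame(participant_id = participant, patient_id = patient,
                    group = group, phase = phase, role = role, dx_code = dx,
                    stringsAsFactors = FALSE)
  out$identified_elements <- list(elements)
  out$invalid_elements <- list(character())
  out
}

# paired student/researcher rows for one participant
plan_pair <- function(participant, student_elements, researcher_elements,
                      group = "control", phase = "pretest", dx = "DX-001") {
  rbind(plan_row(participant, paste0("P-", participant), group, phase,
                 "student", dx, student_elements),
        plan_row(participant, paste0("P-", participant), group, phase,
                 "researcher", dx, researcher_elements))
}
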