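# Shared cohort definition for the analysis scripts.
#
# The synthetic cohort emulates the study design: two strains by two
# session types, four sessions each. Wistars are modeled as proactive
# agents with pre-approach side coding; P rats as reactive agents with
# post-approach side coding. Sessions are cached under scratch/ so the
# numbered scripts can be re-run independently.

library(twocap)

cohort <- expand.grid(strain = c("wistar", "prat"),
                      session_type = c("congruent", "incongruent"),
                      rep = 1:4, stringsAsFactors = FALSE)
cohort$seed <- 100 * seq_len(nrow(cohort))
cohort$id <- sprintf("%s_%s_%d", cohort$strain, cohort$session_type,
                     cohort$rep)

cohort_agent <- function(strain) {
  if (strain == "wistar")
    agent_params(control_mode = "proactive")
  else
    agent_params(control_mode = "reactive")
}

# Wistar populations carry stronger cue-locked activity and pre-approach
# side coding; P rat populations stronger sipper-locked activity and
# post-approach side coding.
cohort_population <- function(strain) {
  if (strain == "wistar")
    population_params(side_code_onset = "pre_approach",
                      cue_gain = 3, sipper_gain = 1.5)
  else
    population_params(side_code_onset = "post_approach",
                      cue_gain = 1.5, sipper_gain = 3)
}

get_session <- function(row) {
  dir.create("scratch/sessions", recursive = TRUE, showWarnings = FALSE)
  path <- file.path("scratch/sessions", paste0(row$id, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  s <- generate_session(session_type = row$session_type,
                        strain = row$strain,
                        agent = cohort_agent(row$strain),
                        pop = cohort_population(row$strain),
                        seed = row$seed)
  saveRDS(s, path)
  s
}

dir.create("results", showWarnings = FALSE)
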