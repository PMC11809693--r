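#!/usr/bin/env Rscript
# Study-design utilities: the Buderer-style sample size behind the study
# and the five canonical solicited-sound script versions. Writes
# results/scripts/script_v*.tsv and prints the design numbers.

suppressPackageStartupMessages(library(coughval))

n <- buderer_sample_size(sensitivity = 0.90, specificity = 0.85,
                         precision = 0.05, prevalence = 0.40,
                         dropout = 0.10, confidence = 0.95)
br <- attr(n, "branches")
cat("Required solicited sounds:", as.integer(n), "\n")
cat(sprintf("  sensitivity branch: %d, specificity branch: %d\n",
            as.integer(br["sensitivity"]), as.integer(br["specificity"])))

dir.create("results/scripts", recursive = TRUE, showWarnings = FALSE)
for (v in 1:5) {
  script <- generate_script(v)
  write_script(script, sprintf("results/scripts/script_v%d.tsv", v))
  cat(sprintf("script v%d: %d instructions, %d coughs (%.0f%% of isolated sounds), total span ~%.0f s\n",
              v, nrow(script), sum(script$kind == "cough") +
                attr(script, "composition")["text_passage_coughs"],
              100 * script_cough_fraction(script),
              sum(script$gap_s + script$duration_s)))
}
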