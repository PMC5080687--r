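# independent duplicate transcription of the reference endpoint tables,
# kept separate from inst/extdata so fixture files are spot-checked against
# a second copy typed by hand
ref_table3 <- data.frame(
  label = c("22:0", "20:2", "18:4", "14:8", "9:13"),
  duration_h = c(28, 28, 28, 28, 25),
  glucose = c(21.85, 19.85, 17.62, 13.35, 8.98),
  glycerol = c(0, 1.83, 3.59, 7.01, 10.94),
  butanol = c(4.33, 4.66, 5.04, 5.38, 5.09),
  isopropanol = c(2.44, 2.24, 2.07, 1.57, 0.83),
  acetone = c(0.28, 0.18, 0, 0, 0),
  acetic_acid = c(0.51, 0.46, 0.43, 0.24, 0.11),
  butyric_acid = c(0.69, 0.73, 0.59, 0.98, 1.95),
  stringsAsFactors = FALSE)

# printed derived rows of the same table
ref_table3_derived <- data.frame(
  label = ref_table3$label,
  total_carbon_mM = c(727.53, 720.43, 703.59, 672.83, 655.27),
  nadph_gen_mM = c(242.51, 259.97, 273.50, 300.36, 337.21),
  nadph_req_mM = c(290.02, 305.35, 319.82, 338.44, 332.62),
  nadph_c = c(0.33, 0.36, 0.39, 0.45, 0.51),
  bi_ratio = c(1.78, 2.07, 2.43, 3.43, 6.14),
  y_b = c(0.20, 0.21, 0.24, 0.26, 0.26),
  y_ib = c(0.31, 0.32, 0.34, 0.34, 0.30),
  stringsAsFactors = FALSE)

# coefficient/mass duplicates for brute-force oracles (typed independently
# of inst/extdata/species_registry.tsv)
ref_masses <- c(glucose = 180.16, glycerol = 92.09, butanol = 74.12,
                isopropanol = 60.10, acetone = 58.08, acetic_acid = 60.05,
                butyric_acid = 88.11)
ref_req_coef <- c(butanol = 4, butyric_acid = 2, isopropanol = 1,
                  acetone = 0, acetic_acid = 0)
ref_gen_coef <- c(glucose = 2, glycerol = 2)

# random-but-valid endpoint generator for property tests
random_record <- function(label = "rand", mixed = TRUE) {
  cons <- c(glucose = stats::runif(1, 2, 30))
  if (mixed && stats::runif(1) < 0.5) {
    cons["glycerol"] <- stats::runif(1, 0.5, 15)
  }
  prods <- c(butanol = stats::runif(1, 0, 6),
             isopropanol = stats::runif(1, 0, 3),
             acetone = stats::runif(1, 0, 0.6),
             acetic_acid = stats::runif(1, 0, 1.5),
             butyric_acid = stats::runif(1, 0, 3))
  # occasionally zero a product out to exercise absent-species paths
  if (stats::runif(1) < 0.3) prods[sample(names(prods), 1)] <- 0
  endpoint_record(label, stats::runif(1, 8, 48), cons, prods)
}

table3_record <- function(label) {
  row <- ref_table3[ref_table3$label == label, ]
  endpoint_record(label, row$duration_h,
                  c(glucose = row$glucose, glycerol = row$glycerol),
                  c(butanol = row$butanol, isopropanol = row$isopropanol,
                    acetone = row$acetone, acetic_acid = row$acetic_acid,
                    butyric_acid = row$butyric_acid))
}
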