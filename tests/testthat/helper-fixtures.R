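# Shared fixtures, built in code.  Heavier simulated objects are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, fully hand-written cohort: 4 samples, 2 genes.
tinyCohort <- function() {
  v <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3", "S3", "S4"),
    gene = c("GA", "GB", "GA", "GA", "GB", "GB"),
    variant_class = c("missense", "synonymous", "missense",
                      "stop_or_frameshift", "missense", "missense"),
    ea = c(80, NA, 40, NA, 50, 20),
    zygosity = c("het", "het", "hom", "het", "het", "het"),
    stringsAsFactors = FALSE)
  s <- data.frame(
    sample_id = paste0("S", 1:4),
    phenotype = c("case", "case", "control", "control"),
    sex = c("female", "male", "female", "male"),
    age = c(70, 75, 68, 80),
    apoe_genotype = c("E3/E4", "E3/E3", "E3/E3", "E2/E3"),
    stringsAsFactors = FALSE)
  EamlCohort(v, s)
}

# Random variant records for one sample x gene cell (pEA oracle tests).
randomCell <- function(n) {
  data.frame(
    variant_class = sample(c("missense", "synonymous",
                             "stop_or_frameshift", "inframe_indel"),
                           n, replace = TRUE,
                           prob = c(0.7, 0.15, 0.1, 0.05)),
    ea = round(runif(n, 0, 100), 2),
    zygosity = sample(c("het", "hom", "hemi"), n, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE)
}

# Independent brute-force pEA oracle: enumerates the product term by term.
bruteForcePEA <- function(records, mode, threshold,
                          hemizygousExponent = 2) {
  prod_term <- 1
  for (i in seq_len(nrow(records))) {
    cls <- records$variant_class[i]
    if (cls == "synonymous") next
    ea <- if (cls %in% c("stop_or_frameshift", "inframe_indel")) 100
          else records$ea[i]
    if (is.na(ea) || ea <= threshold) next
    zy <- records$zygosity[i]
    if (mode == "recessive" && zy == "het") next
    expo <- if (zy == "het") 1 else if (zy == "hom") 2
            else hemizygousExponent
    prod_term <- prod_term * (1 - ea / 100)^expo
  }
  1 - prod_term
}

# Cohort with a perfectly separating gene: every case carries a qualifying
# stop variant in GSEP, no control does.
separableCohort <- function(n_per_class = 30) {
  ids <- sprintf("P%03d", seq_len(2 * n_per_class))
  pheno <- rep(c("case", "control"), each = n_per_class)
  v <- data.frame(
    sample_id = ids[pheno == "case"],
    gene = "GSEP",
    variant_class = "stop_or_frameshift",
    ea = NA_real_,
    zygosity = "het",
    stringsAsFactors = FALSE)
  # background gene so controls have at least one record
  v2 <- data.frame(sample_id = ids, gene = "GBG",
                   variant_class = "missense",
                   ea = 10, zygosity = "het", stringsAsFactors = FALSE)
  s <- data.frame(sample_id = ids, phenotype = pheno, sex = "unknown",
                  age = 70, apoe_genotype = NA_character_,
                  stringsAsFactors = FALSE)
  EamlCohort(rbind(v, v2), s)
}
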