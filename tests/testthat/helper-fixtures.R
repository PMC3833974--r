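# Shared fixtures for the test suite.

# Full five-ingredient baseline list (cohort_spec requires every ingredient
# that simulate_raw_health consults).
base5 <- function(asthma = 0.08, wheeze = 0.10, eczema = 0.08,
                  rhino = 0.08, sens = 0.30) {
  list(asthma_dx_ever = asthma, wheeze_12m = wheeze, eczema_dx = eczema,
       rhino_symptoms_12m = rhino, sensitized = sens)
}

# The canonical 3-object table: o1=(a=0,b=0; unaffected),
# o2=(a=1,b=0; affected), o3=(a=0,b=1; affected).
three_obj_table <- function() {
  decision_table(
    data.frame(a = c("0", "1", "0"), b = c("0", "0", "1"),
               stringsAsFactors = FALSE),
    c("unaffected", "affected", "affected"),
    ids = c("o1", "o2", "o3"))
}

# Perfectly separable table: one decisive binary attribute plus noise.
separable_table <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  cls <- rep(c("affected", "unaffected"), each = n / 2)
  cells <- data.frame(
    p = ifelse(cls == "affected", "1", "0"),
    n1 = sample(c("0", "1"), n, TRUE),
    n2 = sample(c("0", "1", "2"), n, TRUE),
    n3 = sample(c("0", "1"), n, TRUE),
    stringsAsFactors = FALSE)
  decision_table(cells, cls)
}

# Pure-noise binary table with balanced classes.
noise_binary_table <- function(n = 500L, d = 10L, seed = 101L) {
  set.seed(seed)
  cells <- as.data.frame(matrix(sample(c("0", "1"), n * d, TRUE), n),
                         stringsAsFactors = FALSE)
  names(cells) <- sprintf("f%02d", seq_len(d))
  decision_table(cells,
                 sample(rep(c("affected", "unaffected"), each = n / 2)))
}

# Hand-tallied 8-record raw-health fixture (see test-phenotypes.R for the
# full manual tally).
records8 <- function() {
  data.frame(
    asthma_dx_ever     = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE),
    wheeze_12m         = c(TRUE,  FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, FALSE),
    eczema_dx          = c(FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE, TRUE,  FALSE),
    rhino_symptoms_12m = c(TRUE,  FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, FALSE),
    ige_inhalant       = c(0.5,   0.1,   4.0,   0.1,   0.1,   0.2,   0.34,  NA),
    ige_food           = c(0.1,   0.1,   0.2,   0.1,   0.2,   5.0,   0.1,   0.1))
}
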