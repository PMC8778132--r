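# Published reference confusion matrices used as arithmetic worked
# examples: counts with the accompanying two-decimal precision (PRC),
# recall (RCL) and F1 (F1S) readouts. Rows are true classes, columns
# predicted.

# Six lower-limb activities recorded by a shank-mounted 50 Hz IMU
# (HA1 running, HA2 walking, HA3 standing, HA4 sitting, HA5 upstairs,
# HA6 downstairs).
reference_cm_homemade <- function() {
  m <- matrix(c(
    65,   1,  2,   5,  1,  1,
     0, 112,  0,   0,  0,  0,
     0,   1, 97,   1,  0,  0,
     0,   0,  3, 328,  0,  0,
     1,   0,  3,   0, 77,  4,
     1,   0,  1,   0,  1, 75
  ), nrow = 6, byrow = TRUE,
  dimnames = list(paste0("HA", 1:6), paste0("HA", 1:6)))
  as_confusion_matrix(m)
}

reference_homemade_printed <- list(
  recall    = c(0.87, 1.00, 0.98, 0.99, 0.91, 0.96),
  precision = c(0.97, 0.98, 0.92, 0.98, 0.97, 0.94),
  f1        = c(0.92, 0.99, 0.95, 0.99, 0.94, 0.95)
)

# Six activities, 20 Hz smartphone accelerometer (HA1 downstairs,
# HA2 jogging, HA3 sitting, HA4 standing, HA5 upstairs, HA6 walking).
reference_cm_wisdm <- function() {
  m <- matrix(c(
    455,    3,  0,  1,  29,   11,
     10, 1919,  0,  0,   5,    7,
      0,    0, 68,  0,   1,    0,
      0,    0,  0, 53,   0,    0,
     36,   12,  0,  0, 469,   10,
      5,    0,  0,  0,   7, 2049
  ), nrow = 6, byrow = TRUE,
  dimnames = list(paste0("HA", 1:6), paste0("HA", 1:6)))
  as_confusion_matrix(m)
}

# Twelve protocol activities, 100 Hz, 18 IMU channels.
reference_cm_pamap2 <- function() {
  m <- matrix(0L, 12, 12,
              dimnames = list(paste0("HA", 1:12), paste0("HA", 1:12)))
  diag(m) <- c(493, 504, 459, 667, 483, 490, 547, 295, 246, 500, 669, 160)
  m["HA2", "HA1"] <- 46; m["HA2", "HA3"] <- 10
  m["HA3", "HA4"] <- 2
  m["HA5", "HA4"] <- 6; m["HA5", "HA6"] <- 24
  m["HA6", "HA2"] <- 1; m["HA6", "HA4"] <- 1; m["HA6", "HA5"] <- 3
  m["HA6", "HA7"] <- 17
  m["HA8", "HA9"] <- 2
  m["HA9", "HA10"] <- 11
  m["HA10", "HA11"] <- 9
  m["HA11", "HA10"] <- 19
  as_confusion_matrix(m)
}

round_half_up2 <- function(x) floor(x * 100 + 0.5) / 100
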