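# Score constants transcribed from the reference implementations of the
# PAE-based interface metrics. Locked by oracle tests in test-confidence.R;
# do not edit without updating those tests.

# TM-score style size law: d0(n) = 1.24 * (n - 15)^(1/3) - 1.8, clamped below.
.d0_law <- function(n, floor = 1.0) {
  n <- pmax(n, 19)                      # cube root must stay real/positive
  pmax(floor, 1.24 * (n - 15)^(1 / 3) - 1.8)
}

# pDockQ2 sigmoid: L / (1 + exp(-k (x - x0))) + b, with the PAE term using a
# fixed d0 of 10 A over inter-chain interface residue pairs.
.PDOCKQ2_L  <- 1.31034849e+00
.PDOCKQ2_X0 <- 84.733
.PDOCKQ2_K  <- 0.075
.PDOCKQ2_B  <- 0.005
.PDOCKQ2_D0 <- 10.0

# pDockQ (version 1) sigmoid: x = mean interface pLDDT * log(n contacts).
.PDOCKQ_L  <- 0.724
.PDOCKQ_X0 <- 152.611
.PDOCKQ_K  <- 0.052
.PDOCKQ_B  <- 0.018

# Default score parameters.
.PAE_THRESHOLD    <- 10.0   # A; inclusion cutoff for ipSAE
.D0_FLOOR         <- 1.0    # A; lower clamp for the size law
.INTERFACE_CUTOFF <- 8.0    # A; Calpha-Calpha interface rule
.HBOND_CUTOFF     <- 3.5    # A; donor-acceptor heavy-atom distance
.ILE44_CUTOFF     <- 10.0   # A; Closed/Open Ile44-helix cutoff
.TAIL_CUTOFF      <- 12.0   # A; Closed/Open tail-cysteine cutoff (predicted)
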