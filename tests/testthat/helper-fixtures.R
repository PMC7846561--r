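# Shared in-code fixtures: tiny hand-built profiles and reconstructions.

straightTrace <- function(L = 200) rbind(c(-L / 2, 0), c(L / 2, 0))

makeProfile <- function(synapseId = "syn1", sectionIndex = 0L,
                        thickness = 40, condition = "rest",
                        label = "AMPA", halfWidth = 100,
                        gold = NULL, pits = NULL, docked = NULL,
                        offset = c(0, 0)) {
  tr <- rbind(c(-halfWidth, 0), c(halfWidth, 0))
  ProfileAnnotation(synapseId, sectionIndex, thickness, condition, label,
                    azTrace = tr, psdTrace = tr, dockedVesicles = docked,
                    pits = pits, gold = gold, offset = offset)
}

# a 3-section stack with a straight trace in every section
makeStack <- function(synapseId = "synA", nSections = 3L, thickness = 40,
                      halfWidth = 100, goldPerSection = list()) {
  profs <- lapply(seq_len(nSections) - 1L, function(i)
    makeProfile(synapseId, i, thickness, halfWidth = halfWidth,
                gold = goldPerSection[[as.character(i)]]))
  SynapseReconstruction(profs)
}

# brute-force within-cluster SSD minimum by enumerating every assignment
bruteForceSsd <- function(X, k) {
  n <- nrow(X)
  if (k == 1L) {
    ctr <- colMeans(X)
    return(sum(sweep(X, 2, ctr)^2))
  }
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  total <- sum(X^2)
  loss <- rep(total, nrow(A))
  for (j in seq_len(k)) {
    M <- (A == j) * 1
    nj <- rowSums(M)
    sq <- 0
    for (c in seq_len(ncol(X))) sq <- sq + (M %*% X[, c])^2
    contrib <- ifelse(nj > 0, sq / nj, 0)
    loss <- loss - contrib
  }
  min(loss)
}
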