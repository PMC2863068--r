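# Small networks built in code for use across test files.

yn2 <- c("0", "1")

# Pure v-structure A -> C <- B with independent fair parents and a strong,
# non-degenerate CPT for the collision node.
collider_net <- function() {
  bn(c("A", "B", "C"),
     list(A = yn2, B = yn2, C = yn2),
     list(A = character(), B = character(), C = c("A", "B")),
     list(A = cbind(0.5, 0.5), B = cbind(0.5, 0.5),
          C = matrix(c(0.9, 0.1,
                       0.7, 0.3,
                       0.3, 0.7,
                       0.1, 0.9), 4, 2, byrow = TRUE)))
}

# Strong chain A -> B -> C.
chain_net <- function() {
  bn(c("A", "B", "C"),
     list(A = yn2, B = yn2, C = yn2),
     list(A = character(), B = "A", C = "B"),
     list(A = cbind(0.5, 0.5),
          B = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE),
          C = matrix(c(0.85, 0.15, 0.15, 0.85), 2, 2, byrow = TRUE)))
}

# Two-node dependence A -> B.
pair_net <- function(p_flip = 0.1) {
  bn(c("A", "B"),
     list(A = yn2, B = yn2),
     list(A = character(), B = "A"),
     list(A = cbind(0.5, 0.5),
          B = matrix(c(1 - p_flip, p_flip, p_flip, 1 - p_flip),
                     2, 2, byrow = TRUE)))
}
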