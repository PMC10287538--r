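"""Neutral coalescent replicates in ms-style text, via msprime.

Samples are n/2 diploid individuals (n haplotypes), so sizes are diploid
effective population sizes and theta = 4*Ne*mu, the field convention.

Called by the R package as a subprocess; prints one ms block per replicate
(0/1 haplotypes, positions on [0,1)) so the R side can parse it with its own
ms reader. Demography is piecewise-constant: --demography takes
"time:size,time:size,..." population-size changes backward in time.
"""
import argparse
import sys

import msprime
import numpy as np


def main():
    p = argparse.ArgumentParser()
    p.add_argument("--n", type=int, required=True, help="haploid sample size")
    p.add_argument("--length", type=float, required=True)
    p.add_argument("--ne", type=float, required=True)
    p.add_argument("--mu", type=float, required=True)
    p.add_argument("--rho", type=float, required=True)
    p.add_argument("--reps", type=int, default=1)
    p.add_argument("--seed", type=int, required=True)
    p.add_argument("--demography", type=str, default="")
    args = p.parse_args()

    dem = msprime.Demography()
    dem.add_population(name="pop", initial_size=args.ne)
    if args.demography:
        for step in args.demography.split(","):
            t, size = step.split(":")
            dem.add_population_parameters_change(
                time=float(t), initial_size=float(size), population="pop")
    dem.sort_events()

    print(f"ms {args.n} {args.reps} -t . -r . (msprime)")
    print(f"seed: {args.seed}")
    print()

    if args.n % 2 != 0:
        raise SystemExit("haploid sample size must be even "
                         "(samples are diploid individuals)")
    reps = msprime.sim_ancestry(
        samples={"pop": args.n // 2}, ploidy=2,
        sequence_length=args.length, recombination_rate=args.rho,
        demography=dem, num_replicates=args.reps, random_seed=args.seed)
    for i, ts in enumerate(reps):
        mut_seed = (args.seed * 7919 + 104729 * (i + 1)) % 2147483646 + 1
        mts = msprime.sim_mutations(
            ts, rate=args.mu, random_seed=mut_seed,
            model=msprime.BinaryMutationModel(), discrete_genome=False)
        G = mts.genotype_matrix()  # sites x samples, 0/1
        counts = G.sum(axis=1)
        seg = (counts > 0) & (counts < G.shape[1])
        G = G[seg]
        pos = np.array([s.position for s in mts.sites()])[seg] / args.length
        print("//")
        print(f"segsites: {G.shape[0]}")
        if G.shape[0]:
            print("positions: " + " ".join(f"{x:.10f}" for x in pos))
            for h in range(G.shape[1]):
                sys.stdout.write("".join(map(str, G[:, h])) + "\n")
        print()


if __name__ == "__main__":
    main()
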