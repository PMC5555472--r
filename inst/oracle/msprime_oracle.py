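"""Independent coalescent oracle based on msprime.

Reads a JSON spec (path in argv[1]) with scenarios matching the R-side
cross-validation and prints summary statistics as JSON on stdout. Haploid
population sizes are passed directly (msprime ploidy=1, population_size=hapN
gives a pairwise coalescence rate of 1/hapN per generation, matching the
package's convention hapN = 2N_diploid).
"""
import json
import sys

import msprime
import numpy as np


def sim_single_pop(sc, reps, rng):
    S = np.zeros(reps)
    pi = np.zeros(reps)
    for r in range(reps):
        ts = msprime.sim_ancestry(
            samples=int(sc["n"]), ploidy=1,
            population_size=float(sc["hapN"]),
            sequence_length=float(sc["L"]),
            recombination_rate=float(sc.get("rec", 0.0)),
            discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        mts = msprime.sim_mutations(
            ts, rate=float(sc["mu"]), discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        S[r] = mts.num_sites
        pi[r] = mts.diversity(span_normalise=True)
    return S, pi


def sim_im(sc, reps, rng):
    ident = np.zeros(reps)
    for r in range(reps):
        dem = msprime.Demography()
        dem.add_population(name="A", initial_size=float(sc["hapN"]))
        dem.add_population(name="B", initial_size=float(sc["hapN"]))
        dem.add_population(name="ANC", initial_size=float(sc["hapNanc"]))
        dem.set_symmetric_migration_rate(["A", "B"], float(sc["m"]))
        dem.add_population_split(time=float(sc["t_split"]),
                                 derived=["A", "B"], ancestral="ANC")
        ts = msprime.sim_ancestry(
            samples={"A": int(sc["n_A"]), "B": int(sc["n_B"])}, ploidy=1,
            demography=dem,
            sequence_length=float(sc["L"]),
            recombination_rate=float(sc.get("rec", 0.0)),
            discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        mts = msprime.sim_mutations(
            ts, rate=float(sc["mu"]), discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31 - 1)))
        if mts.num_sites == 0:
            ident[r] = 1.0
            continue
        g = mts.genotype_matrix().T  # haplotypes x sites
        nA = int(sc["n_A"])
        keys_a = {tuple(row) for row in g[:nA]}
        keys_b = {tuple(row) for row in g[nA:]}
        ident[r] = 1.0 if keys_a & keys_b else 0.0
    return ident


def main():
    with open(sys.argv[1]) as fh:
        args = json.load(fh)
    reps = int(args["n_replicates"])
    rng = np.random.default_rng(int(args["seed"]))
    out = {}
    for name, sc in args["scenarios"].items():
        if sc["mode"] == "single_pop":
            S, pi = sim_single_pop(sc, reps, rng)
            out[name] = {
                "mean_S": float(S.mean()),
                "se_S": float(S.std(ddof=1) / np.sqrt(reps)),
                "mean_pi": float(pi.mean()),
                "se_pi": float(pi.std(ddof=1) / np.sqrt(reps)),
            }
        else:
            ident = sim_im(sc, reps, rng)
            out[name] = {
                "identity_prob": float(ident.mean()),
                "se_identity": float(ident.std(ddof=1) / np.sqrt(reps)),
            }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
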