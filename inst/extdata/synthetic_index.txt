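# synthetic index fixture (60 records)
9baa  4.13  2012   2.83  IC50=1.479mM   -
2aaa  2.29  2012   2.57  Kd=2.692mM     -
4baa  3.59  2012   2.21  Kd=6.166mM     -
1baa  1.60  2012  10.96  IC50=10.96pM   -
1aaa  4.05  2012  10.50  IC50=31.62pM   -
6faa  1.41  2012   9.80  IC50=158.5pM   flags=incomplete
6daa  1.80  2012  10.30  Kd=50.12pM     -
5faa  3.41  2012   5.49  Ki=3.236uM     flags=covalent
2gaa  3.63  2012   7.73  Ki=18.62nM     flags=non_protein_ligand
4eaa  3.40  2012   3.51  Kd=309uM       -
8aaa  2.23  2012   9.31  Ki=489.8pM     -
7baa  4.06  2012   8.12  Ki=7.586nM     -
6eaa  4.30  2012   8.91  Kd~1.23nM      -
5aaa  2.75  2012   8.34  IC50=4.571nM   -
2faa  NMR  2012   2.36  Kd=4.365mM     -
2baa  4.27  2012   6.04  Kd=912nM       -
3eaa  1.28  2012   6.56  Ki=275.4nM     -
7faa  3.72  2012   8.42  Kd=3.802nM     flags=incomplete
3aaa  3.51  2012   9.25  Kd=562.3pM     -
5baa  2.95  2012   6.02  Kd=955nM       -
6caa  4.09  2012   6.18  IC50=660.7nM   -
1gaa  3.76  2012   5.59  Kd=2.57uM      flags=non_protein_ligand
9aaa  4.18  2012  10.55  IC50=28.18pM   -
1daa  3.97  2012   4.35  IC50=44.67uM   -
2daa  1.20  2012   7.20  IC50=63.1nM    -
4aaa  3.57  2012   3.09  Kd=812.8uM     -
8caa  2.19  2012  10.95  Kd=11.22pM     -
1caa  1.65  2012   2.15  Kd=7.079mM     -
8eaa  2.53  2012   3.51  Kd~309uM       -
3faa  2.15  2012   7.60  IC50=25.12nM   flags=covalent
1faa  NMR  2012   9.19  Kd=645.7pM     -
9daa  3.52  2012   5.93  IC50=1.175uM   -
8baa  1.58  2012   8.20  IC50=6.31nM    -
5eaa  4.17  2012   2.96  IC50>1.096mM   -
3daa  1.27  2012   5.41  Ki=3.89uM      -
7caa  3.91  2012   7.55  Ki=28.18nM     -
8faa  2.74  2012   5.85  Ki=1.413uM     flags=non_protein_ligand
5daa  2.19  2012   5.98  Ki=1.047uM     -
1eaa  1.38  2012   3.34  Ki=457.1uM     -
4gaa  1.85  2012   2.08  IC50=8.318mM   flags=conversion_failed
6aaa  3.58  2012   2.14  Ki=7.244mM     -
7eaa  3.32  2012   9.55  IC50<281.8pM   -
3baa  4.44  2012   2.13  IC50=7.413mM   -
2eaa  4.48  2012   2.12  Kd=7.586mM     -
3gaa  1.27  2012   5.61  Ki=2.455uM     flags=non_protein_ligand
7aaa  2.61  2012   7.13  Ki=74.13nM     -
4caa  1.58  2012   5.15  IC50=7.079uM   -
6gaa  2.15  2012   7.21  IC50=61.66nM   flags=peptide_ge10
9faa  2.86  2012   9.33  IC50=467.7pM   flags=non_protein_ligand
9caa  3.29  2012   6.77  Ki=169.8nM     -
5gaa  2.75  2012   9.14  Kd=724.4pM     flags=uncommon_element
4daa  2.70  2012   5.40  Kd=3.981uM     -
9eaa  NMR  2012   9.26  Kd=549.5pM     -
8daa  3.50  2012   8.78  Ki=1.66nM      -
3caa  1.36  2012   9.84  IC50=144.5pM   -
6baa  2.73  2012   8.86  IC50=1.38nM    -
2caa  2.20  2012   7.40  IC50=39.81nM   -
5caa  3.51  2012   3.02  Kd=955uM       -
7daa  4.51  2012   3.63  IC50=234.4uM   -
4faa  3.42  2012   7.03  IC50=93.33nM   flags=covalent
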