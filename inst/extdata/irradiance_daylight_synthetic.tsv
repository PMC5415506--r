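wavelength	irradiance
300	0.645601
305	0.670818
310	0.695246
315	0.718833
320	0.741533
325	0.763309
330	0.784131
335	0.803975
340	0.822822
345	0.840661
350	0.857484
355	0.873289
360	0.888079
365	0.901859
370	0.91464
375	0.926434
380	0.937257
385	0.947128
390	0.956066
395	0.964093
400	0.971234
405	0.977514
410	0.982958
415	0.987593
420	0.991448
425	0.99455
430	0.996928
435	0.99861
440	0.999625
445	1
450	0.999765
455	0.998947
460	0.997573
465	0.995671
470	0.993267
475	0.990388
480	0.987058
485	0.983302
490	0.979144
495	0.974608
500	0.969716
505	0.96449
510	0.958951
515	0.95312
520	0.947017
525	0.940659
530	0.934066
535	0.927255
540	0.920242
545	0.913045
550	0.905677
555	0.898154
560	0.890491
565	0.882699
570	0.874793
575	0.866783
580	0.858683
585	0.850503
590	0.842253
595	0.833943
600	0.825583
605	0.817181
610	0.808747
615	0.800288
620	0.791811
625	0.783324
630	0.774834
635	0.766346
640	0.757868
645	0.749403
650	0.740958
655	0.732538
660	0.724147
665	0.71579
670	0.70747
675	0.699191
680	0.690957
685	0.682771
690	0.674636
695	0.666555
700	0.65853
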