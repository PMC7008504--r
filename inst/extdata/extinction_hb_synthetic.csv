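wavelength_nm,eps_hbo2_per_mm_per_uM,eps_hhb_per_mm_per_uM
660,0.00010378897,0.00053982472
665,0.00010444835,0.00051746433
670,0.00010521685,0.00049610059
675,0.00010611042,0.0004756945
680,0.00010714661,0.00045621656
685,0.0001083444,0.00043765528
690,0.00010972396,0.00042003247
695,0.00011130624,0.00040342739
700,0.00011311232,0.00038800859
705,0.00011516258,0.00037406626
710,0.0001174756,0.00036202748
715,0.00012006681,0.00035242808
720,0.00012294694,0.00034581358
725,0.00012612038,0.00034255818
730,0.00012958356,0.00034262809
735,0.00013332348,0.00034536325
740,0.0001373168,0.00034938451
745,0.00014152947,0.00035272147
750,0.00014591728,0.00035318557
755,0.00015042725,0.00034890439
760,0.000155,0.00033883948
765,0.00015957275,0.00032308935
770,0.00016408272,0.00030285365
775,0.00016847053,0.00028007368
780,0.0001726832,0.00025689455
785,0.00017667652,0.00023515104
790,0.00018041644,0.0002160405
795,0.00018387962,0.000200044
800,0.00018705306,0.00018705306
805,0.00018993319,0.00017659947
810,0.0001925244,0.00016808518
815,0.00019483742,0.00016094741
820,0.00019688768,0.0001547418
825,0.00019869376,0.00014915939
830,0.00020027604,0.00014400592
835,0.0002016556,0.00013916855
840,0.00020285339,0.000134585
845,0.00020388958,0.00013022124
850,0.00020478315,0.00012605762
855,0.00020555165,0.00012208124
860,0.00020621103,0.00011828231
865,0.00020677565,0.00011465242
870,0.00020725831,0.00011118391
875,0.0002076703,0.00010786954
880,0.00020802152,0.00010470246
885,0.00020832061,0.00010167611
890,0.00020857509,9.8784251e-05
895,0.00020879144,9.6020894e-05
900,0.00020897524,9.3380331e-05
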